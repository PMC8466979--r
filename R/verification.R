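# Categorical forecast verification of risk classes: 4x4 observed-vs-
# predicted contingency tables and the full skill-score suite, plus
# continuous error metrics on the underlying WBGT values.
#
# Convention: counts[a, b] is the number of hours with OBSERVED class a and
# PREDICTED class b (a, b in 0..3), so e.g. C10 = observed 1, predicted 0.
# Scores with an empty denominator are carried as NA ("undefined"), never 0.

#' Build a 4x4 risk-class contingency table
#'
#' Counts paired hourly observed and predicted risk classes. Pairs in which
#' either member is missing are dropped and counted in the `n_dropped`
#' attribute.
#'
#' @param observed,predicted Integer vectors of risk classes in 0..3 (NAs
#'   allowed; incomplete pairs are dropped), equal length.
#' @return A `contingency_table`: a 4x4 integer matrix, rows = observed
#'   class, columns = predicted class, with attribute `n_dropped`.
#' @examples
#' build_contingency(c(1, 2), c(0, 2))
#' @export
build_contingency <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (any(!o %in% 0:3) || any(!p %in% 0:3)) {
    stop("risk classes must lie in 0..3", call. = FALSE)
  }
  counts <- table(factor(o, levels = 0:3), factor(p, levels = 0:3))
  m <- matrix(as.integer(counts), nrow = 4,
              dimnames = list(observed = 0:3, predicted = 0:3))
  structure(m, class = c("contingency_table", "matrix", "array"),
            n_dropped = sum(!ok))
}

#' Coerce a 4x4 count matrix to a contingency table
#' @param x A 4x4 matrix of nonnegative counts (rows observed, cols predicted).
#' @return A `contingency_table`.
#' @export
as_contingency <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(4, 4)) || any(x < 0)) {
    stop("need a 4x4 matrix of nonnegative counts", call. = FALSE)
  }
  structure(matrix(as.numeric(x), nrow = 4,
                   dimnames = list(observed = 0:3, predicted = 0:3)),
            class = c("contingency_table", "matrix", "array"),
            n_dropped = 0L)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Risk-class contingency table (rows observed, cols predicted), n =",
      sum(x), "\n")
  print(unclass(x)[, ])
  invisible(x)
}

#' Merge contingency tables
#'
#' Stratum merging: the table of a concatenated pair stream equals the sum
#' of the stratum tables.
#'
#' @param e1,e2 `contingency_table` objects.
#' @return Their elementwise sum as a `contingency_table`.
#' @export
`+.contingency_table` <- function(e1, e2) {
  out <- unclass(e1) + unclass(e2)
  structure(out, class = class(e1),
            n_dropped = attr(e1, "n_dropped", exact = TRUE) +
              attr(e2, "n_dropped", exact = TRUE))
}

.ct_cell <- function(t, obs, pred) unclass(t)[obs + 1, pred + 1]

.pct_or_na <- function(num, den) {
  if (is.na(den) || den <= 0) NA_real_ else 100 * num / den
}

#' Hit rate
#'
#' Probability (%) of a correct class forecast over all hours, class 0
#' included: `100 * (C00 + C11 + C22 + C33) / n`. With `strict = TRUE` the
#' literal printed denominator (which omits the predicted-class-2 column) is
#' used instead, for audit of the published formula.
#'
#' @param t A `contingency_table`.
#' @param strict Use the literal printed denominator variant.
#' @return Percentage, or `NA` if the denominator is empty.
#' @export
hit_rate <- function(t, strict = FALSE) {
  m <- unclass(t)
  den <- if (strict) sum(m[, -3]) else sum(m)
  .pct_or_na(sum(diag(m)), den)
}

#' Critical success index
#'
#' Probability (%) of a correct forecast among hours involving any risk
#' class (observed or predicted >= 1): `100 * (C11 + C22 + C33) / (n - C00)`.
#' With `strict = TRUE` the literal printed denominator (C02 counted twice,
#' C03 absent) is used, for audit.
#'
#' @inheritParams hit_rate
#' @return Percentage, or `NA` when there are no event hours.
#' @export
critical_success_index <- function(t, strict = FALSE) {
  m <- unclass(t)
  den <- if (strict) {
    sum(m[2:4, 1]) + sum(m[, 2]) + sum(m[, 3]) + m[1, 3] + sum(m[2:4, 4])
  } else {
    sum(m) - m[1, 1]
  }
  .pct_or_na(sum(diag(m)[2:4]), den)
}

#' Probability of detection of a risk class
#'
#' `100 * Ckk / (sum of the observed-class-k row)`. Undefined (`NA`) when no
#' hour was observed in class `k`.
#'
#' @param t A `contingency_table`.
#' @param k Risk class, 1, 2 or 3.
#' @return Percentage or `NA`.
#' @export
pod <- function(t, k) {
  stopifnot(k %in% 1:3)
  m <- unclass(t)
  .pct_or_na(m[k + 1, k + 1], sum(m[k + 1, ]))
}

#' Extended probability of detection
#'
#' Credits a forecast of a higher class as correct. Implemented exactly as
#' published: numerator `C11 + C12` for `k = 1` (a class-3 forecast of an
#' observed class-1 hour is NOT credited by the printed formula) and
#' `C22 + C23` for `k = 2`. `include_higher = TRUE` switches the k = 1
#' numerator to `C11 + C12 + C13`, the variant implied by the verbal
#' definition.
#'
#' @inheritParams pod
#' @param k Risk class, 1 or 2.
#' @param include_higher Credit all higher classes (affects k = 1 only).
#' @return Percentage or `NA`.
#' @export
pod_extended <- function(t, k, include_higher = FALSE) {
  stopifnot(k %in% 1:2)
  m <- unclass(t)
  num <- if (k == 1) {
    m[2, 2] + m[2, 3] + if (include_higher) m[2, 4] else 0
  } else {
    m[3, 3] + m[3, 4]
  }
  .pct_or_na(num, sum(m[k + 1, ]))
}

#' Lack-alarm ratio
#'
#' Probability (%) that an hour forecast as class 0 was in fact observed at
#' a higher class: `100 * (C10 + C20 + C30) / (C00 + C10 + C20 + C30)`.
#'
#' @param t A `contingency_table`.
#' @return Percentage, or `NA` when class 0 was never predicted.
#' @export
lack_alarm <- function(t) {
  m <- unclass(t)
  .pct_or_na(sum(m[2:4, 1]), sum(m[, 1]))
}

#' @describeIn lack_alarm The same numerator normalized by all hours.
#' @export
normalized_lack_alarm <- function(t) {
  m <- unclass(t)
  .pct_or_na(sum(m[2:4, 1]), sum(m))
}

#' False-alarm ratio
#'
#' Probability (%) that an hour observed at class 0 was forecast at a higher
#' class: `100 * (C01 + C02 + C03) / (C00 + C01 + C02 + C03)`.
#'
#' @param t A `contingency_table`.
#' @return Percentage, or `NA` when class 0 was never observed.
#' @export
false_alarm <- function(t) {
  m <- unclass(t)
  .pct_or_na(sum(m[1, 2:4]), sum(m[1, ]))
}

#' @describeIn false_alarm The same numerator normalized by all hours.
#' @export
normalized_false_alarm <- function(t) {
  m <- unclass(t)
  .pct_or_na(sum(m[1, 2:4]), sum(m))
}

#' Observed and predicted class frequencies
#'
#' Marginal shares (%) of each risk class in the observed (row sums) and
#' predicted (column sums) streams; each set sums to 100.
#'
#' @param t A `contingency_table`.
#' @return A tibble with `class`, `observed_pct`, `predicted_pct`.
#' @export
class_frequencies <- function(t) {
  m <- unclass(t)
  n <- sum(m)
  tibble::tibble(
    class = 0:3,
    observed_pct = if (n > 0) unname(100 * rowSums(m) / n)
                   else rep(NA_real_, 4),
    predicted_pct = if (n > 0) unname(100 * colSums(m) / n)
                    else rep(NA_real_, 4)
  )
}

#' Continuous forecast errors
#'
#' Mean error, mean absolute error and root mean square error of a predicted
#' series against an observed one:
#' `ME = mean(Y - O)`, `MAE = mean(|Y - O|)`, `RMSE = sqrt(mean((Y - O)^2))`.
#'
#' @param predicted,observed Equal-length numeric series (NAs allowed in
#'   either; incomplete pairs are dropped).
#' @return A one-row tibble with `me`, `mae`, `rmse`, `n` (all `NA` scores
#'   when no complete pair remains).
#' @examples
#' continuous_errors(c(31, 29), c(30, 30))
#' @export
continuous_errors <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("series must have equal length", call. = FALSE)
  }
  d <- predicted - observed
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    return(tibble::tibble(me = NA_real_, mae = NA_real_, rmse = NA_real_,
                          n = 0L))
  }
  tibble::tibble(me = mean(d), mae = mean(abs(d)),
                 rmse = sqrt(mean(d^2)), n = length(d))
}

#' All categorical skill scores of a contingency table
#'
#' One-row tibble with the full suite: hit rate, critical success index,
#' POD1..3, extended POD1x/POD2x, lack- and false-alarm ratios and their
#' normalized variants, and the sample size. Undefined scores are `NA`.
#'
#' @inheritParams hit_rate
#' @param include_higher Passed to [pod_extended()] for `k = 1`.
#' @return A one-row tibble.
#' @export
skill_scores <- function(t, strict = FALSE, include_higher = FALSE) {
  tibble::tibble(
    n = sum(unclass(t)),
    hr = hit_rate(t, strict = strict),
    csi = critical_success_index(t, strict = strict),
    pod1 = pod(t, 1), pod2 = pod(t, 2), pod3 = pod(t, 3),
    pod1x = pod_extended(t, 1, include_higher = include_higher),
    pod2x = pod_extended(t, 2),
    na = lack_alarm(t), fa = false_alarm(t),
    na_star = normalized_lack_alarm(t), fa_star = normalized_false_alarm(t),
    rlo1 = class_frequencies(t)$observed_pct[2],
    rlo2 = class_frequencies(t)$observed_pct[3],
    rlo3 = class_frequencies(t)$observed_pct[4],
    rlp1 = class_frequencies(t)$predicted_pct[2],
    rlp2 = class_frequencies(t)$predicted_pct[3],
    rlp3 = class_frequencies(t)$predicted_pct[4]
  )
}

#' Stratified skill report with macro-area averages
#'
#' Computes per-station skill scores within each stratum and averages them
#' over geographical macro-areas. The area value of each score is the
#' unweighted mean over the stations of that area for which the score is
#' defined; stations with an undefined score are omitted from that score's
#' mean (the per-score count of contributing stations is reported). Stations
#' flagged `excluded` in the registry never enter area means but keep their
#' per-station rows.
#'
#' @param pairs A data frame of paired hourly classes with columns
#'   `station_id`, `observed_class`, `predicted_class`, and any of the
#'   grouping columns `exposure`, `lead_day`, `slot`, `mode` that are
#'   present.
#' @param registry Station registry with `id`, `area`, `excluded`.
#' @param strict,include_higher Passed to [skill_scores()].
#' @return A list of two tibbles: `stations` (per station x stratum) and
#'   `areas` (per area x stratum, with `n_stations` = stations entering the
#'   mean of at least one score).
#' @export
skill_report <- function(pairs, registry, strict = FALSE,
                         include_higher = FALSE) {
  stopifnot(all(c("station_id", "observed_class", "predicted_class")
                %in% names(pairs)))
  if (anyDuplicated(registry$id) > 0) {
    stop("duplicate station ids in registry", call. = FALSE)
  }
  unknown <- setdiff(unique(pairs$station_id), registry$id)
  if (length(unknown) > 0) {
    stop("station(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  strata <- intersect(c("source", "lead_day", "exposure", "mode", "slot"),
                      names(pairs))
  per_station <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("station_id", strata)))) |>
    dplyr::group_modify(function(d, key) {
      skill_scores(build_contingency(d$observed_class, d$predicted_class),
                   strict = strict, include_higher = include_higher)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      registry |> dplyr::select("id", "area", "excluded"),
      by = c(station_id = "id")
    )
  score_cols <- setdiff(names(skill_scores(as_contingency(diag(4)))), "n")
  per_area <- per_station |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("area", strata)))) |>
    dplyr::summarise(
      n_stations = dplyr::n(),
      n = sum(.data$n),
      dplyr::across(dplyr::all_of(score_cols),
                    list(mean = ~ if (all(is.na(.x))) NA_real_
                         else mean(.x, na.rm = TRUE),
                         n_def = ~ sum(!is.na(.x)))),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("_mean$", "", .x))
  list(stations = per_station, areas = per_area)
}
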