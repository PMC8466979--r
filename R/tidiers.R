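# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contingency table
#'
#' @param x A `contingency_table`.
#' @param ... Unused.
#' @return A long tibble with `observed`, `predicted`, `count`.
#' @method tidy contingency_table
#' @export
tidy.contingency_table <- function(x, ...) {
  m <- unclass(x)
  tidyr::expand_grid(observed = 0:3, predicted = 0:3) |>
    dplyr::mutate(count = as.integer(m[cbind(.data$observed + 1,
                                             .data$predicted + 1)]))
}

#' Summarize a contingency table in one row
#'
#' @param x A `contingency_table`.
#' @param ... Unused.
#' @return A one-row tibble: the full skill-score suite plus `n_dropped`.
#' @method glance contingency_table
#' @export
glance.contingency_table <- function(x, ...) {
  skill_scores(x) |>
    dplyr::mutate(n_dropped = attr(x, "n_dropped", exact = TRUE) %||% 0L)
}

#' Tidy a validation run
#'
#' @param x A `heatrisk_validation` from [run_validation()].
#' @param level `"station"` or `"area"`.
#' @param ... Unused.
#' @return A long tibble with one row per stratum x score: grouping
#'   columns, `score`, `value`.
#' @method tidy heatrisk_validation
#' @export
tidy.heatrisk_validation <- function(x, level = c("station", "area"), ...) {
  level <- match.arg(level)
  d <- if (level == "station") x$scores else x$areas %||% x$area_scores
  score_cols <- intersect(
    c("hr", "csi", "pod1", "pod2", "pod3", "pod1x", "pod2x",
      "na", "fa", "na_star", "fa_star",
      "rlo1", "rlo2", "rlo3", "rlp1", "rlp2", "rlp3"),
    names(d)
  )
  d |>
    tidyr::pivot_longer(dplyr::all_of(score_cols), names_to = "score",
                        values_to = "value")
}

#' Summarize a validation run in one row
#'
#' @param x A `heatrisk_validation`.
#' @param ... Unused.
#' @return One-row tibble: stations verified and skipped, paired records,
#'   overall hit rate and continuous errors pooled over all strata.
#' @method glance heatrisk_validation
#' @export
glance.heatrisk_validation <- function(x, ...) {
  pooled <- build_contingency(x$pairs$observed_class,
                              x$pairs$predicted_class)
  errs <- continuous_errors(x$pairs$wbgt_pred, x$pairs$wbgt_obs)
  tibble::tibble(
    n_stations = length(unique(x$pairs$station_id)),
    n_skipped = nrow(x$skipped),
    n_pairs = nrow(x$pairs),
    hr = hit_rate(pooled),
    csi = critical_success_index(pooled),
    me = errs$me, mae = errs$mae, rmse = errs$rmse
  )
}
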