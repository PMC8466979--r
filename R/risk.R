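# Occupational heat-risk model: effective WBGT for a clothed worker,
# metabolic-rate-dependent reference limits, the four-class risk level, and
# the within-season acclimatization rule.

#' Worker profile
#'
#' Describes the worker for whom risk is assessed. The default is the
#' standard worker used throughout the validation chain: 75 kg, 175 cm,
#' acclimatized to heat, engaged in intense physical activity (metabolic
#' rate 415 W, the high metabolic-rate class of ISO 7243), wearing reference
#' working clothes (clothing adjustment value 0 degrees C).
#'
#' @param weight_kg Body weight, kg.
#' @param height_cm Height, cm.
#' @param mr_w Metabolic rate of the work activity, W; must exceed 1 so the
#'   reference limits are finite and below their analytic intercepts.
#' @param cav_c Clothing adjustment value, degrees C, added to WBGT; >= 0.
#' @param acclimatized Logical; selects the RAL (acclimatized) or REL
#'   (unacclimatized) reference limit.
#' @param label Free-text description.
#' @return A `worker_profile` list.
#' @examples
#' worker_profile()
#' worker_profile(mr_w = 300, acclimatized = FALSE)
#' @export
worker_profile <- function(weight_kg = 75, height_cm = 175, mr_w = 415,
                           cav_c = 0, acclimatized = TRUE,
                           label = "standard worker, intense activity") {
  stopifnot(weight_kg > 0, height_cm > 0)
  if (!is.numeric(mr_w) || mr_w <= 1) {
    stop("`mr_w` must be > 1 W", call. = FALSE)
  }
  if (cav_c < 0) stop("`cav_c` must be >= 0", call. = FALSE)
  structure(
    list(weight_kg = weight_kg, height_cm = height_cm, mr_w = mr_w,
         cav_c = cav_c, acclimatized = isTRUE(acclimatized), label = label),
    class = "worker_profile"
  )
}

#' @export
print.worker_profile <- function(x, ...) {
  cat("Worker profile:", x$label, "\n")
  cat(sprintf("  %g kg, %g cm; MR = %g W; CAV = %g C; %s\n",
              x$weight_kg, x$height_cm, x$mr_w, x$cav_c,
              if (x$acclimatized) "acclimatized" else "unacclimatized"))
  cat(sprintf("  reference limit = %.2f C\n", reference_limit(x)))
  invisible(x)
}

#' Effective WBGT for a clothed worker
#'
#' Adds the clothing adjustment value to the predicted (or observed) WBGT:
#' `WBGT_eff = WBGT + CAV`.
#'
#' @param wbgt WBGT, degrees C.
#' @param cav Clothing adjustment value, degrees C; must be >= 0.
#' @return Effective WBGT, degrees C.
#' @export
effective_wbgt <- function(wbgt, cav) {
  stopifnot(is.finite(wbgt), is.finite(cav))
  if (any(cav < 0)) stop("`cav` must be >= 0", call. = FALSE)
  wbgt + cav
}

#' Reference limits as functions of metabolic rate
#'
#' Screening thresholds on effective WBGT from the metabolic rate MR (W):
#' `ral(MR) = 59.9 - 14.1 * log10(MR)` for an acclimatized worker and
#' `rel(MR) = 56.7 - 11.5 * log10(MR)` for an unacclimatized worker. Both
#' are strictly decreasing in MR; MR = 1 W (where the logarithmic term
#' vanishes) is the analytic intercept of each formula.
#'
#' @param mr Metabolic rate, W; must be >= 1.
#' @return Reference limit, degrees C.
#' @examples
#' ral(100) # 31.7
#' rel(100) # 33.7
#' @export
ral <- function(mr) {
  if (any(!is.finite(mr)) || any(mr < 1)) {
    stop("`mr` must be >= 1 W", call. = FALSE)
  }
  59.9 - 14.1 * log10(mr)
}

#' @rdname ral
#' @export
rel <- function(mr) {
  if (any(!is.finite(mr)) || any(mr < 1)) {
    stop("`mr` must be >= 1 W", call. = FALSE)
  }
  56.7 - 11.5 * log10(mr)
}

#' Reference limit for a worker profile
#'
#' Dispatches to [ral()] when the profile is acclimatized, [rel()] otherwise.
#'
#' @param profile A [worker_profile()].
#' @return Reference limit, degrees C.
#' @export
reference_limit <- function(profile) {
  stopifnot(inherits(profile, "worker_profile"))
  if (profile$acclimatized) ral(profile$mr_w) else rel(profile$mr_w)
}

#' Risk percentage
#'
#' The ratio of effective WBGT to the worker's reference limit, in percent:
#' `RL(%) = 100 * WBGT_eff / limit`.
#'
#' @param wbgt_eff Effective WBGT, degrees C.
#' @param limit Reference limit (RAL or REL), degrees C; must be > 0.
#' @return Risk percentage.
#' @export
risk_percent <- function(wbgt_eff, limit) {
  stopifnot(is.finite(wbgt_eff), is.finite(limit))
  if (any(limit <= 0)) stop("`limit` must be > 0", call. = FALSE)
  100 * wbgt_eff / limit
}

#' Classify the risk percentage into four risk levels
#'
#' Maps RL(%) to the warning classes:
#' \describe{
#'   \item{0 (green)}{RL <= 80, not significant}
#'   \item{1 (yellow)}{80 < RL < 100, low risk}
#'   \item{2 (orange)}{100 <= RL < 120, moderate risk}
#'   \item{3 (red)}{RL >= 120, high risk}
#' }
#' The published inequalities leave RL = 100 unassigned (strict on both
#' sides); here boundaries attach upward, so 100 maps to class 2,
#' consistently with the closed lower bound at 120.
#'
#' @param rl_percent Risk percentage, >= 0.
#' @return Integer vector of classes in 0..3.
#' @examples
#' classify_risk(c(80, 90, 110, 120))
#' @export
classify_risk <- function(rl_percent) {
  if (any(!is.finite(rl_percent)) || any(rl_percent < 0)) {
    stop("`rl_percent` must be finite and >= 0", call. = FALSE)
  }
  as.integer((rl_percent > 80) + (rl_percent >= 100) + (rl_percent >= 120))
}

#' Assess heat risk for a table of WBGT values
#'
#' Chains [effective_wbgt()], [reference_limit()], [risk_percent()] and
#' [classify_risk()] over a data frame, once per requested exposure.
#'
#' @param data A data frame containing `wbgt_shade_c` and/or `wbgt_sun_c`
#'   (as produced by [compute_wbgt()]).
#' @param profile A [worker_profile()].
#' @param exposure Character vector, subset of `c("shade", "sun")`.
#' @return A long tibble: `data` (minus the WBGT columns) repeated per
#'   exposure, with `exposure`, `wbgt_c`, `wbgt_eff_c`, `limit_c`,
#'   `rl_percent`, `rl_class`.
#' @export
assess_risk <- function(data, profile = worker_profile(),
                        exposure = c("shade", "sun")) {
  stopifnot(inherits(profile, "worker_profile"))
  exposure <- match.arg(exposure, several.ok = TRUE)
  lim <- reference_limit(profile)
  cols <- paste0("wbgt_", exposure, "_c")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(data) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "exposure",
                        values_to = "wbgt_c",
                        names_pattern = "wbgt_(.*)_c") |>
    dplyr::mutate(
      wbgt_eff_c = effective_wbgt(.data$wbgt_c, profile$cav_c),
      limit_c = lim,
      rl_percent = pmax(0, risk_percent(.data$wbgt_eff_c, lim)),
      rl_class = classify_risk(.data$rl_percent)
    )
}

#' Acclimatization flag from a daily risk-class series
#'
#' A worker is considered acclimatized once five days with at least moderate
#' risk (daily maximum class >= 2) have accrued within the running warm
#' season. By default qualifying days are counted cumulatively (they need
#' not be consecutive); `consecutive = TRUE` requires an unbroken run of
#' five. The flag turns `TRUE` on the day the fifth qualifying day is
#' reached and, once set, stays set until the next season reset.
#'
#' @param daily_max_class Integer vector of daily maximum risk classes
#'   (0..3), one per calendar day in chronological order.
#' @param dates Optional `Date` vector (same length); must be strictly
#'   increasing. Used to detect season boundaries.
#' @param n_days Number of qualifying days required (default 5).
#' @param consecutive Require the qualifying days to be consecutive?
#' @param season_start_month Month (1..12) at which the count resets when
#'   `dates` are supplied (default 5, May).
#' @return Logical vector: acclimatized from each day onward?
#' @examples
#' update_acclimatization(c(2, 2, 0, 2, 2, 3, 0))
#' @export
update_acclimatization <- function(daily_max_class, dates = NULL,
                                   n_days = 5, consecutive = FALSE,
                                   season_start_month = 5) {
  if (any(!daily_max_class %in% 0:3)) {
    stop("classes must be integers in 0..3", call. = FALSE)
  }
  n <- length(daily_max_class)
  if (!is.null(dates)) {
    stopifnot(inherits(dates, "Date"), length(dates) == n)
    if (is.unsorted(dates, strictly = TRUE)) {
      stop("`dates` must be strictly increasing", call. = FALSE)
    }
    new_season <- c(TRUE, lubridate::month(dates[-1]) == season_start_month &
                      lubridate::month(dates[-n]) != season_start_month |
                      diff(lubridate::year(dates)) > 0)
    season <- cumsum(new_season)
  } else {
    season <- rep(1L, n)
  }
  qualifying <- daily_max_class >= 2
  out <- logical(n)
  for (s in unique(season)) {
    idx <- which(season == s)
    q <- qualifying[idx]
    count <- if (consecutive) {
      # length of the qualifying run ending at each day
      Reduce(function(acc, x) if (x) acc + 1 else 0, q, accumulate = TRUE)
    } else {
      cumsum(q)
    }
    out[idx] <- cummax(as.integer(count >= n_days)) == 1L
  }
  out
}
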