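# Psychrometrics and the Wet Bulb Globe Temperature (WBGT) heat-stress index.
#
# WBGT combines the natural wet-bulb temperature (Tnwb, a wetted sensor
# exposed to actual wind and radiation), the black-globe temperature (Tg,
# inside a 150 mm matt-black globe) and the dry-bulb air temperature (Ta):
#   shade: WBGT = 0.7 Tnwb + 0.3 Tg
#   sun:   WBGT = 0.7 Tnwb + 0.2 Tg + 0.1 Ta
# Neither Tnwb nor Tg is reported by weather stations or forecast models, so
# both are estimated here from standard hourly variables (Ta, RH, wind,
# downward shortwave radiation).

# Psychrometer constant, hPa/K, ~1000 hPa ventilated psychrometer
.GAMMA_PSY <- 0.667
# Stefan-Boltzmann constant, W m-2 K-4
.SIGMA_SB <- 5.670374419e-8
# 150 mm globe: diameter m, shortwave absorptivity, longwave emissivity
.GLOBE_D <- 0.15
.GLOBE_ALPHA <- 0.95
.GLOBE_EPS <- 0.95
# wind floor (m/s) below which the convection/wind-function formulas are
# evaluated at the floor; the parameterizations are undefined at calm
.WIND_FLOOR <- 0.1

#' Saturation vapor pressure over water
#'
#' Magnus-form saturation vapor pressure with WMO coefficients,
#' `6.112 * exp(17.62 * ta / (243.12 + ta))`.
#'
#' @param ta Dry-bulb air temperature, degrees C. Must be finite.
#' @return Saturation vapor pressure in hPa, same length as `ta`.
#' @examples
#' saturation_vapor_pressure(c(0, 20, 35))
#' @export
saturation_vapor_pressure <- function(ta) {
  if (!is.numeric(ta) || any(!is.finite(ta))) {
    stop("`ta` must be finite numeric (got ",
         paste(utils::head(ta[!is.finite(ta)], 3), collapse = ", "), ")",
         call. = FALSE)
  }
  6.112 * exp(17.62 * ta / (243.12 + ta))
}

#' Relative humidity from dew point
#'
#' Some networks report dew point rather than relative humidity; this
#' converts it for use with the WBGT chain.
#'
#' @param ta Dry-bulb temperature, degrees C.
#' @param td Dew-point temperature, degrees C; must not exceed `ta`.
#' @return Relative humidity in percent (0, 100].
#' @export
dewpoint_to_rh <- function(ta, td) {
  if (any(td > ta + 1e-9)) {
    stop("dew point exceeds air temperature", call. = FALSE)
  }
  pmin(100, 100 * saturation_vapor_pressure(td) / saturation_vapor_pressure(ta))
}

# Vectorized bisection: f must be vectorized and change sign on [lo, hi].
# Returns the root to within `tol` (interval half-width), at most `maxit`
# halvings; errors with the offending indices if the bracket is invalid.
.bisect <- function(f, lo, hi, tol = 1e-3, maxit = 100L) {
  flo <- f(lo)
  fhi <- f(hi)
  bad <- flo * fhi > 0
  if (any(bad)) {
    stop("root not bracketed for record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (all(hi - lo < tol)) break
    fmid <- f(mid)
    take_lo <- flo * fmid <= 0
    hi <- ifelse(take_lo, mid, hi)
    fhi <- ifelse(take_lo, fmid, fhi)
    lo <- ifelse(take_lo, lo, mid)
    flo <- ifelse(take_lo, flo, fmid)
  }
  (lo + hi) / 2
}

.check_meteo_scalar_inputs <- function(ta, rh, wind = 0, solar = 0) {
  if (any(!is.finite(ta)) || any(!is.finite(rh)) ||
      any(!is.finite(wind)) || any(!is.finite(solar))) {
    stop("meteorological inputs must be finite", call. = FALSE)
  }
  if (any(rh <= 0 | rh > 100)) {
    stop("`rh` must lie in (0, 100]: wet-bulb temperature is undefined at ",
         "the dry limit", call. = FALSE)
  }
  if (any(wind < 0)) stop("`wind` must be >= 0", call. = FALSE)
  if (any(solar < 0)) stop("`solar` must be >= 0", call. = FALSE)
  invisible(TRUE)
}

# Clamp wind to the documented floor, optionally messaging how many records
# were clamped (the formulas are log/power laws undefined at calm).
.clamp_wind <- function(wind, quiet = TRUE) {
  n_clamped <- sum(wind < .WIND_FLOOR)
  if (n_clamped > 0 && !quiet) {
    message(n_clamped, " wind value(s) below ", .WIND_FLOOR,
            " m/s clamped to the floor")
  }
  pmax(wind, .WIND_FLOOR)
}

#' Psychrometric (aspirated) wet-bulb temperature
#'
#' Solves the psychrometric balance
#' `e_s(tw) - gamma * (ta - tw) = e` for `tw` by bisection, where `e` is the
#' ambient vapor pressure `rh/100 * e_s(ta)` and `gamma` the psychrometer
#' constant (0.667 hPa/K). The root is found to 1e-3 degrees C.
#'
#' @param ta Dry-bulb temperature, degrees C.
#' @param rh Relative humidity, percent, in (0, 100].
#' @return Wet-bulb temperature, degrees C; equals `ta` at saturation.
#' @examples
#' psychrometric_wet_bulb(30, 50)
#' @export
psychrometric_wet_bulb <- function(ta, rh) {
  .check_meteo_scalar_inputs(ta, rh)
  n <- max(length(ta), length(rh))
  ta <- rep_len(ta, n)
  rh <- rep_len(rh, n)
  e <- rh / 100 * saturation_vapor_pressure(ta)
  f <- function(tw) {
    saturation_vapor_pressure(tw) - .GAMMA_PSY * (ta - tw) - e
  }
  tw <- .bisect(f, lo = ta - 80, hi = ta, tol = 1e-4)
  # exactly saturated air: wet bulb equals dry bulb by definition
  ifelse(rh == 100, ta, tw)
}

#' Black-globe temperature from meteorological variables
#'
#' Estimates the temperature of a 150 mm black globe by solving its steady
#' energy balance: absorbed shortwave (`alpha * S / 4`, the sphere's
#' projected-to-total area ratio) plus net longwave exchange with
#' surroundings at air temperature balances forced convection
#' (`h = 6.3 * v^0.6 / d^0.4`, the standard sphere correlation). Solved by
#' bisection to 1e-3 degrees C. At zero shortwave flux the balance returns
#' the air temperature.
#'
#' @inheritParams psychrometric_wet_bulb
#' @param wind Wind speed, m/s; values below 0.1 m/s are clamped to 0.1.
#' @param solar Downward shortwave radiation, W/m2.
#' @param quiet Suppress the message reporting wind-floor clamps.
#' @return Globe temperature, degrees C.
#' @examples
#' black_globe_temperature(30, 50, 1, 900)
#' @export
black_globe_temperature <- function(ta, rh, wind, solar, quiet = TRUE) {
  .check_meteo_scalar_inputs(ta, rh, wind, solar)
  n <- max(length(ta), length(rh), length(wind), length(solar))
  ta <- rep_len(ta, n); wind <- rep_len(wind, n); solar <- rep_len(solar, n)
  v <- .clamp_wind(wind, quiet = quiet)
  h <- 6.3 * v^0.6 / .GLOBE_D^0.4
  ta_k <- ta + 273.15
  f <- function(tg) {
    tg_k <- tg + 273.15
    .GLOBE_ALPHA * solar / 4 +
      .GLOBE_EPS * .SIGMA_SB * (ta_k^4 - tg_k^4) -
      h * (tg - ta)
  }
  tg <- .bisect(f, lo = ta, hi = ta + 80, tol = 1e-4)
  # no shortwave load: surroundings at Ta make Tg = Ta exactly
  ifelse(solar == 0, ta, tg)
}

#' Natural wet-bulb temperature in shade or in sun
#'
#' The natural wet bulb (a wetted sensor in the actual wind and radiation) is
#' estimated from the psychrometric wet bulb with the Bernard wind function:
#' `Tnwb = Ta - C(v) * (Ta - Tpwb)` where
#' `C(v) = 0.96 + 0.069 * log10(v)` clamped to `[0.85, 1]` (the published
#' low- and high-wind regimes; the clamping keeps the function continuous).
#' Under direct sun the radiant load on the wick adds
#' `0.25 * (Tg - Ta)`, with `Tg` from [black_globe_temperature()].
#'
#' @inheritParams black_globe_temperature
#' @param exposure `"shade"` or `"sun"`.
#' @return Natural wet-bulb temperature, degrees C. The shade value lies
#'   between the psychrometric wet bulb and `ta`; the sun value is at least
#'   the shade value whenever `solar > 0`.
#' @examples
#' natural_wet_bulb(32, 60, 1, 800, "sun")
#' @export
natural_wet_bulb <- function(ta, rh, wind, solar,
                             exposure = c("shade", "sun"), quiet = TRUE) {
  exposure <- match.arg(exposure)
  .check_meteo_scalar_inputs(ta, rh, wind, solar)
  v <- .clamp_wind(wind, quiet = quiet)
  tpwb <- psychrometric_wet_bulb(ta, rh)
  cv <- pmin(1, pmax(0.85, 0.96 + 0.069 * log10(v)))
  tnwb <- ta - cv * (ta - tpwb)
  if (exposure == "sun") {
    tg <- black_globe_temperature(ta, rh, wind, solar, quiet = quiet)
    tnwb <- tnwb + 0.25 * (tg - ta)
  }
  tnwb
}

#' WBGT composition without direct sun
#'
#' `0.7 * tnwb + 0.3 * tg`: the natural wet bulb carries 70% of the index,
#' the globe the remaining 30%.
#'
#' @param tnwb Natural wet-bulb temperature, degrees C.
#' @param tg Black-globe temperature, degrees C.
#' @return WBGT, degrees C.
#' @export
wbgt_shade <- function(tnwb, tg) {
  stopifnot(is.finite(tnwb), is.finite(tg))
  0.7 * tnwb + 0.3 * tg
}

#' WBGT composition under direct sun
#'
#' `0.7 * tnwb + 0.2 * tg + 0.1 * ta`.
#'
#' @inheritParams wbgt_shade
#' @param ta Dry-bulb temperature, degrees C.
#' @return WBGT, degrees C.
#' @export
wbgt_sun <- function(tnwb, tg, ta) {
  stopifnot(is.finite(tnwb), is.finite(tg), is.finite(ta))
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}

#' Compute sun and shade WBGT for a table of hourly records
#'
#' Adds the estimated WBGT components and both index variants to a data frame
#' of hourly meteorological records. The shade index uses a globe shielded
#' from shortwave radiation (so its globe temperature equals the air
#' temperature); the sun index uses the irradiated globe and the sun-exposed
#' natural wet bulb.
#'
#' @param data A data frame with columns `ta_c`, `rh_pct`, `wind_ms`,
#'   `solar_wm2` (and any others, which are kept).
#' @param quiet Suppress wind-floor clamp messages.
#' @return A tibble: `data` plus `tnwb_c` (sun-exposed natural wet bulb),
#'   `tg_c` (irradiated globe), `wbgt_shade_c`, `wbgt_sun_c`.
#' @examples
#' df <- tibble::tibble(ta_c = 32, rh_pct = 55, wind_ms = 1.2, solar_wm2 = 780)
#' compute_wbgt(df)
#' @export
compute_wbgt <- function(data, quiet = TRUE) {
  req <- c("ta_c", "rh_pct", "wind_ms", "solar_wm2")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ta <- data$ta_c; rh <- data$rh_pct
  wind <- data$wind_ms; solar <- data$solar_wm2
  tnwb_shade <- natural_wet_bulb(ta, rh, wind, solar, "shade", quiet = quiet)
  tg <- black_globe_temperature(ta, rh, wind, solar, quiet = quiet)
  tnwb_sun <- tnwb_shade + 0.25 * (tg - ta)
  tibble::as_tibble(data) |>
    dplyr::mutate(
      tnwb_c = tnwb_sun,
      tg_c = tg,
      wbgt_shade_c = wbgt_shade(tnwb_shade, ta),
      wbgt_sun_c = wbgt_sun(tnwb_sun, tg, ta)
    )
}

#' Flag implausible meteorological records
#'
#' Checks each record against plausibility windows and adds a `qc_flag`
#' column naming the first violated rule (`NA` for clean records). Records
#' are flagged, never dropped.
#'
#' @param data Data frame with `ta_c`, `rh_pct`, `wind_ms`, `solar_wm2`.
#' @param ta_range Plausibility window for air temperature, degrees C.
#' @return `data` as a tibble with a `qc_flag` character column.
#' @export
flag_meteo <- function(data, ta_range = c(-30, 55)) {
  tibble::as_tibble(data) |>
    dplyr::mutate(
      qc_flag = dplyr::case_when(
        !is.finite(.data$ta_c) | !is.finite(.data$rh_pct) |
          !is.finite(.data$wind_ms) | !is.finite(.data$solar_wm2) ~ "missing",
        .data$ta_c < ta_range[1] | .data$ta_c > ta_range[2] ~ "ta_range",
        .data$rh_pct <= 0 | .data$rh_pct > 100 ~ "rh_range",
        .data$wind_ms < 0 ~ "wind_negative",
        .data$solar_wm2 < 0 ~ "solar_negative",
        TRUE ~ NA_character_
      )
    )
}
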