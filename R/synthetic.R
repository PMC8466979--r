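# Synthetic station networks and paired observed/forecast hourly series with
# a known, controllable error structure. The generator emulates the study
# design the package validates: a 28-station network over three Italian
# macro-areas (A north inland plains, B coastal, C central-south inland),
# May-September hourly series, and 00 UTC forecast runs with 72 h of hourly
# leads whose grid points may sit at a different elevation than the station.
# It is plumbing for verification, not a weather model: solar uses a
# day-length-aware half-sine envelope, not a radiative transfer scheme, and
# stations are independent given their area parameters.

#' Synthetic scenario
#'
#' Parameters of the synthetic network and error model. Defaults describe a
#' Mediterranean warm season: area mean temperatures and diurnal amplitudes
#' decrease from inland plains (A) through coastal (B) to a slightly hotter
#' central-south inland area (C) only via their means; humidity cycles
#' anti-phase with temperature; wind is log-normal; solar follows a
#' clear-sky half-sine modulated by an autocorrelated cloud factor.
#'
#' @param n_stations Integer vector, stations per macro-area A, B, C
#'   (default `c(7, 12, 9)`, 28 total).
#' @param start,end Season span (Dates). Default May 1 - Sep 30.
#' @param year Season year used when `start`/`end` are NULL.
#' @param area_params Named list per area with `ta_mean` (seasonal mean
#'   daily-mean temperature, C), `ta_diurnal` (half peak-to-trough diurnal
#'   amplitude, C), `ta_seasonal` (half amplitude of the seasonal cycle, C),
#'   `rh_mean` (%), `rh_diurnal` (%), `wind_meanlog`, `wind_sdlog`
#'   (log m/s), `solar_peak` (clear-sky noon flux, W/m2).
#' @param ar1_sd,ar1_rho Residual AR(1) innovation sd (C) and lag-1
#'   correlation of the hourly temperature residual.
#' @param cloud_sd AR(1) innovation sd of the logit cloud factor.
#' @param error_model A [forecast_error_model()].
#' @param complex_station Add one complex-topography station to area A whose
#'   matched grid point sits `complex_elev_offset_m` higher than the
#'   station (excluded from area means, like a narrow-valley site where the
#'   model reconstructs a much higher elevation).
#' @param complex_elev_offset_m Grid-minus-station elevation of that
#'   station, m (default +788, i.e. roughly a 262 m valley floor seen by the
#'   model at about 1050 m).
#' @param elev_offset_sd Standard deviation (m) of the ordinary stations'
#'   grid-minus-station elevation offsets.
#' @param seed Integer seed; fully determines the output.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_stations = c(A = 7, B = 12, C = 9),
                               start = NULL, end = NULL, year = 2019,
                               area_params = NULL,
                               ar1_sd = 0.8, ar1_rho = 0.8,
                               cloud_sd = 0.5,
                               error_model = forecast_error_model(),
                               complex_station = TRUE,
                               complex_elev_offset_m = 788,
                               elev_offset_sd = 30,
                               seed = 1L) {
  if (is.null(start)) start <- as.Date(sprintf("%d-05-01", year))
  if (is.null(end)) end <- as.Date(sprintf("%d-09-30", year))
  if (is.null(area_params)) {
    area_params <- list(
      A = list(ta_mean = 23, ta_diurnal = 6.0, ta_seasonal = 4.5,
               rh_mean = 60, rh_diurnal = 18, wind_meanlog = 0.1,
               wind_sdlog = 0.5, solar_peak = 880, lat = 45.5, lon = 10.5,
               alt_range = c(30, 300)),
      B = list(ta_mean = 24, ta_diurnal = 4.0, ta_seasonal = 4.0,
               rh_mean = 68, rh_diurnal = 12, wind_meanlog = 0.5,
               wind_sdlog = 0.5, solar_peak = 900, lat = 40.5, lon = 12.5,
               alt_range = c(3, 150)),
      C = list(ta_mean = 24.5, ta_diurnal = 7.0, ta_seasonal = 4.5,
               rh_mean = 55, rh_diurnal = 20, wind_meanlog = 0.0,
               wind_sdlog = 0.5, solar_peak = 900, lat = 42.5, lon = 11.5,
               alt_range = c(5, 250))
    )
  }
  stopifnot(length(n_stations) == 3, all(n_stations >= 1),
            ar1_sd >= 0, cloud_sd >= 0, abs(ar1_rho) < 1)
  structure(list(n_stations = n_stations, start = start, end = end,
                 area_params = area_params, ar1_sd = ar1_sd,
                 ar1_rho = ar1_rho, cloud_sd = cloud_sd,
                 error_model = error_model,
                 complex_station = complex_station,
                 complex_elev_offset_m = complex_elev_offset_m,
                 elev_offset_sd = elev_offset_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Forecast error model
#'
#' Additive error structure imposed on the observed series to fabricate a
#' forecast: per-variable constant bias plus AR(1) noise, and a lapse-rate
#' cooling proportional to the grid-minus-station elevation offset applied
#' to temperature (`-lapse_rate_c_per_100m * elev_offset_m / 100`).
#'
#' @param bias Named numeric: additive bias for `ta` (C), `rh` (%),
#'   `wind` (m/s), `solar` (W/m2).
#' @param noise_sd Named numeric, AR(1) innovation standard deviations.
#' @param noise_rho Lag-1 autocorrelation shared by the error processes.
#' @param lapse_rate_c_per_100m Temperature lapse rate, C per 100 m.
#' @return A `forecast_error_model` list.
#' @export
forecast_error_model <- function(bias = c(ta = 0, rh = 0, wind = 0,
                                          solar = 0),
                                 noise_sd = c(ta = 0.8, rh = 5, wind = 0.3,
                                              solar = 60),
                                 noise_rho = 0.6,
                                 lapse_rate_c_per_100m = 0.65) {
  vars <- c("ta", "rh", "wind", "solar")
  bias <- bias[vars]; bias[is.na(bias)] <- 0; names(bias) <- vars
  noise_sd <- noise_sd[vars]; noise_sd[is.na(noise_sd)] <- 0
  names(noise_sd) <- vars
  stopifnot(all(noise_sd >= 0), abs(noise_rho) < 1)
  structure(list(bias = bias, noise_sd = noise_sd, noise_rho = noise_rho,
                 lapse_rate_c_per_100m = lapse_rate_c_per_100m),
            class = "forecast_error_model")
}

# deterministic per-station sub-seed so adding a station never perturbs the
# streams of the others; kept below 2^31
.station_seed <- function(seed, station_id, salt = 0L) {
  h <- sum(utf8ToInt(paste0(station_id, ":", salt)) *
             seq_along(utf8ToInt(paste0(station_id, ":", salt))))
  (as.integer(seed) * 2654435L + h * 97L) %% 2147483629L
}

.ar1 <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(rep(0, n))
  as.numeric(stats::arima.sim(list(ar = rho), n = n,
                              sd = sd * sqrt(1 - rho^2)))
}

#' Generate a synthetic station network
#'
#' Lays out the configured number of stations per macro-area with plausible
#' coordinates and altitudes, plus (by default) one complex-topography
#' station in area A with a large imposed grid-elevation error, flagged
#' `excluded` so it never enters area means.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A registry tibble: `id`, `name`, `lat`, `lon`, `alt_m`, `area`,
#'   `excluded`, `grid_elev_offset_m`.
#' @examples
#' generate_station_network(synthetic_scenario())
#' @export
generate_station_network <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  rows <- purrr::imap(scenario$area_params, function(p, area) {
    n <- scenario$n_stations[[area]]
    tibble::tibble(
      id = sprintf("%s%02d", area, seq_len(n)),
      name = sprintf("station_%s%02d", area, seq_len(n)),
      lat = p$lat + stats::runif(n, -1.5, 1.5),
      lon = p$lon + stats::runif(n, -1.5, 1.5),
      alt_m = round(stats::runif(n, p$alt_range[1], p$alt_range[2])),
      area = area,
      excluded = FALSE,
      grid_elev_offset_m = round(stats::rnorm(n, 0, scenario$elev_offset_sd))
    )
  })
  reg <- dplyr::bind_rows(rows)
  if (scenario$complex_station) {
    # narrow-valley analogue: first area-A station gets the large offset
    i <- which(reg$area == "A")[1]
    reg$grid_elev_offset_m[i] <- scenario$complex_elev_offset_m
    reg$excluded[i] <- TRUE
    reg$name[i] <- paste0(reg$name[i], "_valley")
  }
  reg
}

#' Generate an observed hourly series for one station
#'
#' Hourly temperature = seasonal cycle + diurnal sinusoid (peak mid
#' afternoon) + AR(1) residual; relative humidity anti-phased with the
#' diurnal cycle, clipped to (0, 100]; wind log-normal with mild diurnal
#' modulation; solar a day-length-aware clear-sky half-sine times an
#' autocorrelated cloud factor, zero at night.
#'
#' @param station One registry row.
#' @param scenario A [synthetic_scenario()].
#' @return A tibble: `station_id`, `timestamp_local` (POSIXct Europe/Rome),
#'   `ta_c`, `rh_pct`, `wind_ms`, `solar_wm2`.
#' @export
generate_observed_series <- function(station,
                                     scenario = synthetic_scenario()) {
  p <- scenario$area_params[[station$area]]
  set.seed(.station_seed(scenario$seed, station$id, salt = 1L))
  times <- seq(lubridate::force_tz(lubridate::as_datetime(scenario$start),
                                   "Europe/Rome"),
               lubridate::force_tz(lubridate::as_datetime(scenario$end) +
                                     lubridate::dhours(23), "Europe/Rome"),
               by = "1 hour")
  n <- length(times)
  doy <- lubridate::yday(times)
  hour <- lubridate::hour(times)
  # seasonal cycle peaking around late July (doy 207)
  seasonal <- p$ta_seasonal * cos(2 * pi * (doy - 207) / 365)
  diurnal <- p$ta_diurnal * cos(2 * pi * (hour - 15) / 24)
  ta <- p$ta_mean + seasonal + diurnal +
    .ar1(n, scenario$ar1_sd, scenario$ar1_rho) -
    0.0065 * station$alt_m # altitude cooling relative to sea-level mean
  # humidity anti-phased with the diurnal temperature wave
  rh <- p$rh_mean - p$rh_diurnal * cos(2 * pi * (hour - 15) / 24) +
    .ar1(n, 4, scenario$ar1_rho)
  rh <- pmin(100, pmax(5, rh))
  wind <- exp(p$wind_meanlog + 0.2 * cos(2 * pi * (hour - 14) / 24) +
                stats::rnorm(n, 0, p$wind_sdlog))
  # day-length-aware half-sine clear-sky envelope times a cloud factor
  half_day <- 6 + 2 * cos(2 * pi * (doy - 172) / 365) # ~8 h midsummer
  x <- (hour - 13) / half_day # solar noon ~13 local daylight-saving time
  clear <- ifelse(abs(x) < 1, p$solar_peak * cospi(x / 2)^2, 0)
  cloud_logit <- .ar1(n, scenario$cloud_sd, 0.9) + 1.5
  cloud <- stats::plogis(cloud_logit)
  tibble::tibble(
    station_id = station$id,
    timestamp_local = times,
    ta_c = ta,
    rh_pct = rh,
    wind_ms = pmax(0, wind),
    solar_wm2 = clear * cloud
  )
}

#' Fabricate a forecast series from an observed one
#'
#' Applies the configured error structure to the observed stream and wraps
#' it in 00 UTC / 72 h-lead run metadata: for each run day, lead hours 0..71
#' map to the observed values at the corresponding valid times plus bias,
#' AR(1) noise and (for temperature) the lapse-rate effect of the station's
#' grid-elevation offset. Variables are clipped to their physical ranges
#' afterwards.
#'
#' @param obs Observed series from [generate_observed_series()].
#' @param station The registry row (for `grid_elev_offset_m`).
#' @param error_model A [forecast_error_model()].
#' @param seed Integer seed for the error draws.
#' @param n_lead_h Lead horizon, hours (default 72).
#' @return A tibble: `station_id`, `source`, `run_time_utc`, `lead_h`,
#'   `grid_elev_m`, `ta_c`, `rh_pct`, `wind_ms`, `solar_wm2`.
#' @export
generate_forecast_series <- function(obs, station,
                                     error_model = forecast_error_model(),
                                     seed = 1L, n_lead_h = 72L) {
  stopifnot(inherits(error_model, "forecast_error_model"))
  set.seed(.station_seed(seed, station$id, salt = 2L))
  em <- error_model
  lapse_dt <- -em$lapse_rate_c_per_100m * station$grid_elev_offset_m / 100
  run_days <- sort(unique(lubridate::as_date(obs$timestamp_local)))
  runs <- lubridate::force_tz(lubridate::as_datetime(run_days), "UTC")
  grid <- tidyr::expand_grid(run_time_utc = runs, lead_h = 0:(n_lead_h - 1)) |>
    dplyr::mutate(valid_time_local =
                    lubridate::with_tz(.data$run_time_utc, "Europe/Rome") +
                    lubridate::dhours(.data$lead_h))
  joined <- grid |>
    dplyr::inner_join(obs, by = c(valid_time_local = "timestamp_local"))
  n <- nrow(joined)
  err <- function(v) em$bias[[v]] + .ar1(n, em$noise_sd[[v]], em$noise_rho)
  joined |>
    dplyr::mutate(
      station_id = station$id,
      source = "SYN",
      grid_elev_m = station$alt_m + station$grid_elev_offset_m,
      ta_c = .data$ta_c + lapse_dt + err("ta"),
      rh_pct = pmin(100, pmax(1, .data$rh_pct + err("rh"))),
      wind_ms = pmax(0, .data$wind_ms + err("wind")),
      solar_wm2 = ifelse(.data$solar_wm2 > 0,
                         pmax(0, .data$solar_wm2 + err("solar")),
                         0)
    ) |>
    dplyr::select("station_id", "source", "run_time_utc", "lead_h",
                  "grid_elev_m", "ta_c", "rh_pct", "wind_ms", "solar_wm2")
}

#' Generate the full synthetic network dataset
#'
#' Convenience wrapper: registry plus stacked observed and forecast tables
#' for every station in the scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of tibbles `registry`, `obs`, `fcst`.
#' @export
generate_dataset <- function(scenario = synthetic_scenario()) {
  registry <- generate_station_network(scenario)
  obs <- purrr::map(seq_len(nrow(registry)), function(i) {
    generate_observed_series(registry[i, ], scenario)
  })
  fcst <- purrr::map(seq_len(nrow(registry)), function(i) {
    generate_forecast_series(obs[[i]], registry[i, ],
                             error_model = scenario$error_model,
                             seed = scenario$seed)
  })
  list(registry = registry,
       obs = dplyr::bind_rows(obs),
       fcst = dplyr::bind_rows(fcst))
}

#' Class-pair sequences realizing an exact contingency table
#'
#' Emits shuffled observed/predicted class sequences whose contingency table
#' equals the target exactly; an oracle fixture for the verification module.
#'
#' @param target A 4x4 matrix (or `contingency_table`) of nonnegative
#'   integer counts, rows observed, columns predicted.
#' @param seed Integer seed for the shuffle.
#' @return A tibble with `observed_class` and `predicted_class`.
#' @examples
#' tab <- diag(c(10, 10, 10, 10))
#' pairs <- generate_classified_pair(tab)
#' build_contingency(pairs$observed_class, pairs$predicted_class)
#' @export
generate_classified_pair <- function(target, seed = 1L) {
  m <- unclass(as_contingency(target))
  if (any(m != round(m))) stop("target counts must be integers",
                               call. = FALSE)
  idx <- which(m > 0, arr.ind = TRUE)
  o <- rep(idx[, 1] - 1L, times = m[idx])
  p <- rep(idx[, 2] - 1L, times = m[idx])
  set.seed(seed)
  ord <- sample.int(length(o))
  tibble::tibble(observed_class = as.integer(o[ord]),
                 predicted_class = as.integer(p[ord]))
}
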