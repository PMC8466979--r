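# Readers and writers for the package's plain-text CSV dialects, and
# YAML configuration loading. All temperatures are degrees C, humidity %,
# wind m/s, radiation W/m2 - enforced at the reader boundary: rows with
# out-of-range values are quarantined (returned in an attribute with line
# numbers), never silently dropped or passed through.

.OBS_COLS <- c("station_id", "timestamp_local", "ta_c", "rh_pct",
               "wind_ms", "solar_wm2")
.FCST_COLS <- c("station_id", "source", "run_time_utc", "lead_h",
                "grid_elev_m", "ta_c", "rh_pct", "wind_ms", "solar_wm2")
.REG_COLS <- c("id", "name", "lat", "lon", "alt_m", "area", "excluded")

.quarantine <- function(data, bad, what) {
  good <- data[!bad, , drop = FALSE]
  q <- data[bad, , drop = FALSE]
  if (nrow(q) > 0) {
    q$line <- which(bad) + 1L # header is line 1
    message(nrow(q), " ", what, " row(s) quarantined")
  }
  attr(good, "quarantined") <- q
  good
}

#' Read an observed hourly meteorological CSV
#'
#' Dialect: header `station_id,timestamp_local,ta_c,rh_pct,wind_ms,solar_wm2`,
#' ISO-8601 timestamps, empty fields for missing values. Rows with
#' out-of-range values (RH outside (0, 100], negative wind or radiation,
#' temperature outside the plausibility window) are quarantined into the
#' `quarantined` attribute with their line numbers.
#'
#' @param path CSV file path.
#' @param tz Time zone the local timestamps refer to.
#' @param ta_range Air-temperature plausibility window, degrees C.
#' @return A tibble of valid records (attribute `quarantined`).
#' @export
read_observed <- function(path, tz = "Europe/Rome",
                          ta_range = c(-30, 55)) {
  d <- readr::read_csv(path, col_types = readr::cols(
    station_id = readr::col_character(),
    timestamp_local = readr::col_datetime(),
    ta_c = readr::col_double(), rh_pct = readr::col_double(),
    wind_ms = readr::col_double(), solar_wm2 = readr::col_double()
  ))
  missing_cols <- setdiff(.OBS_COLS, names(d))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$timestamp_local <- lubridate::force_tz(d$timestamp_local, tz)
  bad <- !is.na(d$rh_pct) & (d$rh_pct <= 0 | d$rh_pct > 100) |
    !is.na(d$wind_ms) & d$wind_ms < 0 |
    !is.na(d$solar_wm2) & d$solar_wm2 < 0 |
    !is.na(d$ta_c) & (d$ta_c < ta_range[1] | d$ta_c > ta_range[2])
  .quarantine(d, bad, "observed")
}

#' Read a forecast CSV
#'
#' Dialect: header `station_id,source,run_time_utc,lead_h,grid_elev_m,ta_c,
#' rh_pct,wind_ms,solar_wm2`; run times ISO-8601 UTC. Out-of-range rows are
#' quarantined as in [read_observed()].
#'
#' @inheritParams read_observed
#' @return A tibble of valid records (attribute `quarantined`).
#' @export
read_forecast <- function(path, ta_range = c(-30, 55)) {
  d <- readr::read_csv(path, col_types = readr::cols(
    station_id = readr::col_character(),
    source = readr::col_character(),
    run_time_utc = readr::col_datetime(),
    lead_h = readr::col_integer(),
    grid_elev_m = readr::col_double(),
    ta_c = readr::col_double(), rh_pct = readr::col_double(),
    wind_ms = readr::col_double(), solar_wm2 = readr::col_double()
  ))
  missing_cols <- setdiff(.FCST_COLS, names(d))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$run_time_utc <- lubridate::force_tz(d$run_time_utc, "UTC")
  bad <- !is.na(d$rh_pct) & (d$rh_pct <= 0 | d$rh_pct > 100) |
    !is.na(d$wind_ms) & d$wind_ms < 0 |
    !is.na(d$solar_wm2) & d$solar_wm2 < 0 |
    !is.na(d$ta_c) & (d$ta_c < ta_range[1] | d$ta_c > ta_range[2]) |
    is.na(d$lead_h) | d$lead_h < 0
  .quarantine(d, bad, "forecast")
}

#' Read a station registry CSV
#'
#' Dialect: `id,name,lat,lon,alt_m,area,excluded` with area one of A
#' (north inland plains), B (coastal), C (central-south inland).
#'
#' @param path CSV file path.
#' @return A registry tibble.
#' @export
read_registry <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), name = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double(),
    alt_m = readr::col_double(), area = readr::col_character(),
    excluded = readr::col_logical()
  ))
  missing_cols <- setdiff(.REG_COLS, names(d))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!d$area %in% c("A", "B", "C"))) {
    stop("`area` must be one of A, B, C", call. = FALSE)
  }
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180)) {
    stop("invalid coordinates in registry", call. = FALSE)
  }
  d
}

#' Write package CSV dialects
#'
#' Writers matching [read_observed()], [read_forecast()] and
#' [read_registry()]; timestamps are serialized as ISO-8601 so the files
#' round-trip exactly.
#'
#' @param data The table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observed <- function(data, path) {
  out <- data |>
    dplyr::mutate(timestamp_local = format(.data$timestamp_local,
                                           "%Y-%m-%dT%H:%M:%S")) |>
    dplyr::select(dplyr::all_of(.OBS_COLS))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_observed
#' @export
write_forecast <- function(data, path) {
  out <- data |>
    dplyr::mutate(run_time_utc = format(.data$run_time_utc,
                                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) |>
    dplyr::select(dplyr::all_of(.FCST_COLS))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_observed
#' @export
write_registry <- function(data, path) {
  readr::write_csv(dplyr::select(data, dplyr::all_of(.REG_COLS)), path,
                   na = "")
  invisible(path)
}

#' Load a validation run configuration from YAML
#'
#' Reads a config file with optional blocks `validation` (fields of
#' [validation_config()]) and `worker` (fields of [worker_profile()]).
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A [validation_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("validation", "worker"))
  if (length(unknown) > 0) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  wargs <- raw$worker %||% list()
  bad_w <- setdiff(names(wargs), names(formals(worker_profile)))
  if (length(bad_w) > 0) {
    stop("unknown worker key(s): ", paste(bad_w, collapse = ", "),
         call. = FALSE)
  }
  profile <- do.call(worker_profile, wargs)
  vargs <- raw$validation %||% list()
  bad_v <- setdiff(names(vargs), names(formals(validation_config)))
  if (length(bad_v) > 0) {
    stop("unknown validation key(s): ", paste(bad_v, collapse = ", "),
         call. = FALSE)
  }
  vargs$profile <- profile
  do.call(validation_config, vargs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
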