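# Study-design pipeline: pair stations with forecast grid points, slice
# hourly series by season / time slot / forecast lead day, compute WBGT and
# risk classes on the observed and forecast streams, and drive verification.
#
# All slot logic runs in local civil time (daylight saving in season);
# forecast valid times, archived at UTC, are shifted to local time before
# slicing. The default time zone is Europe/Rome.

#' Validation configuration
#'
#' Collects the knobs of a validation run.
#'
#' @param season_months Integer months analysed (default May-September).
#' @param slots Slot start hours; with 24 appended they must partition the
#'   day into half-open `[start, end)` local-time intervals.
#' @param lead_days Forecast lead days to verify: 1 = the run's start
#'   calendar day (flagged, as it gives less than 24 h of warning),
#'   2 = tomorrow, 3 = the day after.
#' @param exposures Subset of `c("shade", "sun")`.
#' @param profile A [worker_profile()].
#' @param modes Analysis modes: `"all-hours"` keeps every paired hour,
#'   `"slot-max"` reduces each slot to the pair of WBGT maxima (classified
#'   independently).
#' @param min_hours_all,min_hours_max Minimum complete paired hours for a
#'   slot to enter the all-hours / slot-max analysis (defaults 5 and 6 of 6).
#' @param min_valid_fraction Station-level quality gate: minimum fraction of
#'   season hours with valid pairs for a station to be verified.
#' @param tz Time zone for local civil time.
#' @return A `validation_config` list.
#' @export
validation_config <- function(season_months = 5:9,
                              slots = c(0, 6, 12, 18),
                              lead_days = 2,
                              exposures = c("shade", "sun"),
                              profile = worker_profile(),
                              modes = c("all-hours", "slot-max"),
                              min_hours_all = 5, min_hours_max = 6,
                              min_valid_fraction = 0.8,
                              tz = "Europe/Rome") {
  slots <- as.integer(slots)
  bounds <- c(slots, 24L)
  if (anyDuplicated(slots) > 0 || slots[1] != 0L ||
      any(diff(bounds) <= 0) || any(bounds > 24L)) {
    stop("slot starts must begin at 0 and partition the 24 h day",
         call. = FALSE)
  }
  if (!all(lead_days %in% 1:3)) stop("lead days must be 1, 2 or 3",
                                     call. = FALSE)
  modes <- match.arg(modes, several.ok = TRUE)
  exposures <- match.arg(exposures, c("shade", "sun"), several.ok = TRUE)
  structure(list(season_months = season_months, slots = slots,
                 lead_days = sort(lead_days), exposures = exposures,
                 profile = profile, modes = modes,
                 min_hours_all = min_hours_all, min_hours_max = min_hours_max,
                 min_valid_fraction = min_valid_fraction, tz = tz),
            class = "validation_config")
}

#' Match a station to its nearest forecast grid point
#'
#' Nearest-neighbour extraction: the grid point at minimum great-circle
#' (haversine) distance from the station, with no correction of any kind;
#' ties broken by lowest grid index, deterministically. The elevation
#' difference between the grid point and the station is recorded because it
#' drives systematic temperature errors in complex topography.
#'
#' @param station One-row data frame (or list) with `lat`, `lon`, `alt_m`.
#' @param grid A data frame of grid points with `grid_lat`, `grid_lon`,
#'   `grid_elev_m`.
#' @return A one-row tibble: the matched grid point plus `distance_m` and
#'   `elev_diff_m` (grid minus station).
#' @export
match_grid_point <- function(station, grid) {
  if (is.null(grid) || nrow(grid) == 0) {
    stop("empty grid", call. = FALSE)
  }
  d <- geosphere::distHaversine(
    cbind(station$lon, station$lat),
    cbind(grid$grid_lon, grid$grid_lat)
  )
  i <- which.min(d) # which.min takes the first minimum: lowest-index tie rule
  tibble::as_tibble(grid[i, , drop = FALSE]) |>
    dplyr::mutate(distance_m = d[i],
                  elev_diff_m = .data$grid_elev_m - station$alt_m)
}

#' Extract one forecast lead day as local calendar hours
#'
#' From a forecast run (00 UTC, 72 h of hourly leads) returns the rows whose
#' valid time falls on the requested local calendar day: day 1 is the run's
#' start day in local time, day 2 the next day, day 3 the day after.
#'
#' @param fcst Forecast rows of a single run, with `run_time_utc` (POSIXct,
#'   UTC) and `lead_h`.
#' @param day_index 1, 2 or 3.
#' @param tz Local time zone.
#' @return The matching rows with `valid_time_local` (POSIXct) added. Day 1
#'   extraction emits a warning: it provides less than 24 h of advance
#'   notice, so it is not suitable for an alert system.
#' @export
extract_lead_day <- function(fcst, day_index, tz = "Europe/Rome") {
  if (!day_index %in% 1:3) stop("`day_index` must be 1, 2 or 3",
                                call. = FALSE)
  if (day_index == 1) {
    warning("day-1 extraction gives < 24 h of warning; ",
            "not suitable for an alert system", call. = FALSE)
  }
  run <- unique(fcst$run_time_utc)
  if (length(run) != 1) stop("`fcst` must hold a single run", call. = FALSE)
  valid_local <- lubridate::with_tz(run, tz) + lubridate::dhours(fcst$lead_h)
  target_day <- lubridate::as_date(lubridate::with_tz(run, tz)) +
    (day_index - 1)
  keep <- lubridate::as_date(valid_local) == target_day
  if (!any(keep)) {
    stop("run does not cover requested day ", day_index,
         " (horizon too short)", call. = FALSE)
  }
  out <- tibble::as_tibble(fcst[keep, , drop = FALSE])
  out$valid_time_local <- valid_local[keep]
  out
}

#' Assign hourly records to daily time slots
#'
#' Each hour is assigned to exactly one half-open local-time slot
#' `[start, end)`; with the default bounds 0-6, 6-12, 12-18, 18-24, hour
#' 12:00 falls in slot "12-18". A `slot_n` count per day x slot is attached
#' so incomplete slots can be filtered downstream.
#'
#' @param data Data frame with a POSIXct local-time column.
#' @param slots Slot start hours partitioning the day (see
#'   [validation_config()]).
#' @param time_col Name of the local-time column.
#' @return `data` with `slot` (factor "0-6", ...), `date` and `slot_n`.
#' @export
slice_time_slots <- function(data, slots = c(0, 6, 12, 18),
                             time_col = "timestamp_local") {
  bounds <- c(as.integer(slots), 24L)
  if (anyDuplicated(slots) > 0 || bounds[1] != 0L || any(diff(bounds) <= 0)) {
    stop("slots must partition 0-24 without overlap", call. = FALSE)
  }
  labels <- paste0(utils::head(bounds, -1), "-", bounds[-1])
  tt <- data[[time_col]]
  hr <- lubridate::hour(tt)
  tibble::as_tibble(data) |>
    dplyr::mutate(
      slot = factor(labels[findInterval(hr, bounds[-length(bounds)])],
                    levels = labels),
      date = lubridate::as_date(tt)
    ) |>
    dplyr::add_count(.data$date, .data$slot, name = "slot_n")
}

#' Reduce a sliced stream to analysis records
#'
#' In `"all-hours"` mode every paired hour passes through (slots with fewer
#' than `min_hours` complete pairs are dropped and counted). In `"slot-max"`
#' mode each day x slot is reduced to one record holding the observed
#' maximum and the predicted maximum of the value column, taken
#' independently (they may come from different hours).
#'
#' @param data Output of [slice_time_slots()] with paired value columns.
#' @param mode `"all-hours"` or `"slot-max"`.
#' @param obs_col,pred_col Names of the paired value columns.
#' @param min_hours Completeness threshold per slot.
#' @return A tibble of analysis records; dropped-slot count in attribute
#'   `n_slots_dropped`.
#' @export
slot_reduce <- function(data, mode = c("all-hours", "slot-max"),
                        obs_col = "wbgt_obs", pred_col = "wbgt_pred",
                        min_hours = if (mode == "slot-max") 6 else 5) {
  mode <- match.arg(mode)
  complete <- !is.na(data[[obs_col]]) & !is.na(data[[pred_col]])
  d <- tibble::as_tibble(data[complete, , drop = FALSE]) |>
    dplyr::add_count(.data$date, .data$slot, name = "n_complete")
  kept <- d |> dplyr::filter(.data$n_complete >= min_hours)
  n_dropped <- nrow(dplyr::distinct(d, .data$date, .data$slot)) -
    nrow(dplyr::distinct(kept, .data$date, .data$slot))
  out <- if (mode == "all-hours") {
    kept
  } else {
    kept |>
      dplyr::group_by(.data$date, .data$slot) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(c(obs_col, pred_col)), max),
        n_hours = dplyr::n(), .groups = "drop"
      )
  }
  attr(out, "n_slots_dropped") <- n_dropped
  out
}

# classify a wbgt vector for a profile: returns integer classes
.classify_wbgt <- function(wbgt, profile) {
  lim <- reference_limit(profile)
  classify_risk(pmax(0, risk_percent(effective_wbgt(wbgt, profile$cav_c),
                                     lim)))
}

#' Run the full validation chain
#'
#' For every station x exposure x lead day x slot x mode stratum: pair the
#' observed hourly stream with the forecast stream valid on that lead day,
#' compute WBGT on both, classify risk for the configured worker, build the
#' contingency table, compute all skill scores and continuous WBGT errors,
#' and average per macro-area. Deterministic given inputs and config.
#'
#' @param obs Observed hourly records: `station_id`, `timestamp_local`
#'   (POSIXct), `ta_c`, `rh_pct`, `wind_ms`, `solar_wm2`.
#' @param fcst Forecast records: `station_id`, `source`, `run_time_utc`
#'   (POSIXct, UTC), `lead_h`, `ta_c`, `rh_pct`, `wind_ms`, `solar_wm2`.
#' @param registry Station registry: `id`, `name`, `lat`, `lon`, `alt_m`,
#'   `area`, `excluded`.
#' @param config A [validation_config()].
#' @return A `heatrisk_validation` object: list with `scores` (per-station
#'   categorical scores), `area_scores`, `errors` (per-station continuous
#'   WBGT errors), `area_errors`, `skipped` (stations without forecasts or
#'   failing the quality gate), and `config`.
#' @export
run_validation <- function(obs, fcst, registry, config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  profile <- config$profile
  tz <- config$tz

  have_fcst <- unique(fcst$station_id)
  skipped <- registry |>
    dplyr::filter(!.data$id %in% have_fcst) |>
    dplyr::mutate(reason = "no matched forecast") |>
    dplyr::select("id", "reason")

  obs <- obs |>
    dplyr::filter(lubridate::month(.data$timestamp_local) %in%
                    config$season_months)

  # WBGT on both streams, then risk classes per exposure
  obs_w <- compute_wbgt(obs)
  fcst <- fcst |>
    dplyr::mutate(valid_time_local =
                    lubridate::with_tz(.data$run_time_utc, tz) +
                    lubridate::dhours(.data$lead_h),
                  run_day_local =
                    lubridate::as_date(lubridate::with_tz(.data$run_time_utc,
                                                          tz)),
                  lead_day = as.integer(
                    lubridate::as_date(.data$valid_time_local) -
                      .data$run_day_local) + 1L) |>
    dplyr::filter(.data$lead_day %in% config$lead_days,
                  lubridate::month(.data$valid_time_local) %in%
                    config$season_months)
  fcst_w <- compute_wbgt(fcst)

  pair_rows <- list()
  for (src in unique(fcst_w$source)) {
    for (ld in config$lead_days) {
      f_ld <- fcst_w |>
        dplyr::filter(.data$source == src, .data$lead_day == ld) |>
        dplyr::select("station_id", "valid_time_local",
                      fcst_shade = "wbgt_shade_c", fcst_sun = "wbgt_sun_c")
      paired <- obs_w |>
        dplyr::select("station_id", "timestamp_local",
                      obs_shade = "wbgt_shade_c", obs_sun = "wbgt_sun_c") |>
        dplyr::inner_join(f_ld,
                          by = c("station_id", timestamp_local =
                                   "valid_time_local")) |>
        slice_time_slots(config$slots)
      for (expo in config$exposures) {
        oc <- paste0("obs_", expo); pc <- paste0("fcst_", expo)
        for (mode in config$modes) {
          min_h <- if (mode == "slot-max") config$min_hours_max
                   else config$min_hours_all
          red <- paired |>
            dplyr::group_by(.data$station_id) |>
            dplyr::group_modify(~ slot_reduce(.x, mode, oc, pc,
                                              min_hours = min_h)) |>
            dplyr::ungroup() |>
            dplyr::mutate(
              observed_class = .classify_wbgt(.data[[oc]], profile),
              predicted_class = .classify_wbgt(.data[[pc]], profile),
              source = src, lead_day = ld, exposure = expo, mode = mode
            )
          pair_rows[[length(pair_rows) + 1L]] <-
            red |> dplyr::select("station_id", "source", "lead_day",
                                 "exposure", "mode", "slot",
                                 "observed_class", "predicted_class",
                                 wbgt_obs = dplyr::all_of(oc),
                                 wbgt_pred = dplyr::all_of(pc))
        }
      }
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)

  # station-level quality gate: fraction of season hours with valid pairs
  if (nrow(pairs) > 0 && config$min_valid_fraction > 0) {
    n_days_total <- obs_w |>
      dplyr::mutate(date = lubridate::as_date(.data$timestamp_local)) |>
      dplyr::distinct(.data$station_id, .data$date) |>
      dplyr::count(.data$station_id, name = "n_days")
    gate2 <- pairs |>
      dplyr::filter(.data$mode == "all-hours") |>
      dplyr::count(.data$station_id, .data$source, .data$lead_day,
                   .data$exposure, name = "n_pairs") |>
      dplyr::group_by(.data$station_id) |>
      dplyr::summarise(n_pairs = max(.data$n_pairs), .groups = "drop") |>
      dplyr::left_join(n_days_total, by = "station_id") |>
      dplyr::mutate(frac = .data$n_pairs / (24 * .data$n_days)) |>
      dplyr::filter(.data$frac < config$min_valid_fraction)
    if (nrow(gate2) > 0) {
      skipped <- dplyr::bind_rows(
        skipped,
        tibble::tibble(id = gate2$station_id, reason = "quality gate")
      )
      pairs <- pairs |>
        dplyr::filter(!.data$station_id %in% gate2$station_id)
    }
  }

  strata <- c("source", "lead_day", "exposure", "mode", "slot")
  report <- skill_report(pairs |> dplyr::select(-"wbgt_obs", -"wbgt_pred"),
                         registry)
  errors <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("station_id", strata)))) |>
    dplyr::summarise(continuous_errors(.data$wbgt_pred, .data$wbgt_obs),
                     .groups = "drop") |>
    dplyr::left_join(registry |> dplyr::select("id", "area", "excluded"),
                     by = c(station_id = "id"))
  area_errors <- errors |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("area", strata)))) |>
    dplyr::summarise(n_stations = dplyr::n(), n = sum(.data$n),
                     me = mean(.data$me), mae = mean(.data$mae),
                     rmse = mean(.data$rmse), .groups = "drop")

  structure(
    list(scores = report$stations, area_scores = report$areas,
         errors = errors, area_errors = area_errors,
         pairs = pairs, skipped = skipped, config = config),
    class = "heatrisk_validation"
  )
}

#' @export
print.heatrisk_validation <- function(x, ...) {
  cat("Heat-risk forecast validation\n")
  cat("  stations verified:", length(unique(x$scores$station_id)),
      " skipped:", nrow(x$skipped), "\n")
  cat("  strata (source x lead x exposure x mode x slot):",
      nrow(dplyr::distinct(x$scores |>
        dplyr::select(dplyr::any_of(c("source", "lead_day", "exposure",
                                      "mode", "slot"))))), "\n")
  cat("  paired records:", nrow(x$pairs), "\n")
  invisible(x)
}
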