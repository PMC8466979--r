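# Synthetic network and error-structure generators.

test_that("the default network reproduces the study layout deterministically", {
  reg <- generate_station_network(synthetic_scenario())
  expect_equal(nrow(reg), 28) # 7 + 12 + 9
  expect_equal(as.vector(table(reg$area)), c(7, 12, 9))
  # areas partition the station set
  expect_equal(anyDuplicated(reg$id), 0)
  expect_true(all(reg$area %in% c("A", "B", "C")))
  # one complex-topography station in area A, excluded from area means
  expect_equal(sum(reg$excluded), 1)
  valley <- reg[reg$excluded, ]
  expect_equal(valley$area, "A")
  expect_equal(valley$grid_elev_offset_m, 788)
  # same seed twice: identical registry
  expect_identical(reg, generate_station_network(synthetic_scenario()))
  # different seed: different coordinates
  reg2 <- generate_station_network(synthetic_scenario(seed = 2))
  expect_false(all(reg$lat == reg2$lat))
})

test_that("observed series obey their construction in the noise-free limit", {
  sc <- synthetic_scenario(start = as.Date("2019-06-01"),
                           end = as.Date("2019-06-05"),
                           ar1_sd = 0, cloud_sd = 0, seed = 5)
  reg <- generate_station_network(sc)
  s <- generate_observed_series(reg[1, ], sc)
  expect_equal(nrow(s), 5 * 24)
  # solar is zero at local midnight, positive near solar noon
  hrs <- lubridate::hour(s$timestamp_local)
  expect_true(all(s$solar_wm2[hrs == 0] == 0))
  expect_true(all(s$solar_wm2[hrs == 13] > 0))
  # noise-free temperature peaks at the configured hour (15 local)
  one_day <- s[lubridate::day(s$timestamp_local) == 3, ]
  expect_equal(lubridate::hour(one_day$timestamp_local[
    which.max(one_day$ta_c)]), 15)
  # humidity anti-phased: driest at the warm peak
  expect_equal(lubridate::hour(one_day$timestamp_local[
    which.min(one_day$rh_pct)]), 15)
  expect_true(all(s$rh_pct > 0 & s$rh_pct <= 100))
  expect_true(all(s$wind_ms >= 0))
  # determinism under the seed
  expect_identical(s, generate_observed_series(reg[1, ], sc))
})

test_that("per-station substreams are stable when stations are added", {
  sc1 <- synthetic_scenario(n_stations = c(A = 1, B = 1, C = 1),
                            start = as.Date("2019-06-01"),
                            end = as.Date("2019-06-03"), seed = 9,
                            complex_station = FALSE)
  sc2 <- synthetic_scenario(n_stations = c(A = 2, B = 1, C = 1),
                            start = as.Date("2019-06-01"),
                            end = as.Date("2019-06-03"), seed = 9,
                            complex_station = FALSE)
  st <- list(id = "B01", area = "B", alt_m = 10)
  s1 <- generate_observed_series(st, sc1)
  s2 <- generate_observed_series(st, sc2)
  expect_identical(s1$ta_c, s2$ta_c)
})

test_that("the long-run temperature mean recovers the scenario mean", {
  # Monte Carlo over seasons: the all-hours mean of the diurnal and
  # seasonal sinusoids over May-September is approximately the scenario
  # mean minus the altitude cooling
  means <- sapply(1:20, function(seed) {
    sc <- synthetic_scenario(start = as.Date("2019-05-01"),
                             end = as.Date("2019-09-30"), seed = seed,
                             complex_station = FALSE)
    st <- list(id = "A01", area = "A", alt_m = 0)
    mean(generate_observed_series(st, sc)$ta_c)
  })
  sc0 <- synthetic_scenario()
  expected <- sc0$area_params$A$ta_mean +
    mean(sc0$area_params$A$ta_seasonal *
           cos(2 * pi * ((121:273) - 207) / 365))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 0.1)
})

test_that("forecast fabrication recovers injected bias and lapse effects", {
  sc <- identity_scenario(days = 6, seed = 13)
  reg <- generate_station_network(sc)
  obs <- generate_observed_series(reg[1, ], sc)
  # zero-error model: forecast equals the observation at each valid time
  f0 <- generate_forecast_series(obs, reg[1, ], sc$error_model, seed = 13)
  j0 <- dplyr::inner_join(
    f0 |> dplyr::mutate(valid = lubridate::with_tz(run_time_utc,
                                                   "Europe/Rome") +
                          lubridate::dhours(lead_h)),
    obs, by = c(valid = "timestamp_local"), suffix = c("_f", "_o")
  )
  expect_equal(j0$ta_c_f, j0$ta_c_o, tolerance = 1e-12)
  # +2 C bias, no noise: ME(Ta) = 2 exactly
  em <- forecast_error_model(bias = c(ta = 2),
                             noise_sd = c(ta = 0, rh = 0, wind = 0,
                                          solar = 0))
  f2 <- generate_forecast_series(obs, reg[1, ], em, seed = 13)
  j2 <- dplyr::inner_join(
    f2 |> dplyr::mutate(valid = lubridate::with_tz(run_time_utc,
                                                   "Europe/Rome") +
                          lubridate::dhours(lead_h)),
    obs, by = c(valid = "timestamp_local"), suffix = c("_f", "_o")
  )
  expect_equal(continuous_errors(j2$ta_c_f, j2$ta_c_o)$me, 2,
               tolerance = 1e-12)
  # +788 m grid elevation with 0.65 C/100 m lapse: Ta depressed ~5.1 C
  st_valley <- reg[1, ]
  st_valley$grid_elev_offset_m <- 788
  fv <- generate_forecast_series(obs, st_valley,
                                 forecast_error_model(
                                   noise_sd = c(ta = 0, rh = 0, wind = 0,
                                                solar = 0)), seed = 13)
  jv <- dplyr::inner_join(
    fv |> dplyr::mutate(valid = lubridate::with_tz(run_time_utc,
                                                   "Europe/Rome") +
                          lubridate::dhours(lead_h)),
    obs, by = c(valid = "timestamp_local"), suffix = c("_f", "_o")
  )
  expect_equal(continuous_errors(jv$ta_c_f, jv$ta_c_o)$me,
               -0.65 * 788 / 100, tolerance = 1e-9)
})

test_that("stochastic bias is recovered within sampling error over many seeds", {
  true_bias <- 1.5
  em <- forecast_error_model(bias = c(ta = true_bias),
                             noise_sd = c(ta = 0.8, rh = 0, wind = 0,
                                          solar = 0), noise_rho = 0.6)
  est <- sapply(1:50, function(seed) {
    sc <- synthetic_scenario(n_stations = c(A = 1, B = 1, C = 1),
                             start = as.Date("2019-06-01"),
                             end = as.Date("2019-06-10"),
                             complex_station = FALSE, elev_offset_sd = 0,
                             seed = seed)
    reg <- generate_station_network(sc)
    obs <- generate_observed_series(reg[1, ], sc)
    f <- generate_forecast_series(obs, reg[1, ], em, seed = seed)
    j <- dplyr::inner_join(
      f |> dplyr::mutate(valid = lubridate::with_tz(run_time_utc,
                                                    "Europe/Rome") +
                           lubridate::dhours(lead_h)),
      obs, by = c(valid = "timestamp_local"), suffix = c("_f", "_o")
    )
    continuous_errors(j$ta_c_f, j$ta_c_o)$me
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_bias), 3 * se)
})

test_that("increasing temperature bias degrades WBGT error monotonically", {
  sc <- identity_scenario(days = 8, seed = 17)
  ds <- generate_dataset(sc)
  me_by_bias <- sapply(c(0, 1, 2), function(b) {
    em <- forecast_error_model(bias = c(ta = b),
                               noise_sd = c(ta = 0, rh = 0, wind = 0,
                                            solar = 0))
    f <- dplyr::bind_rows(lapply(seq_len(nrow(ds$registry)), function(i) {
      obs_i <- ds$obs[ds$obs$station_id == ds$registry$id[i], ]
      generate_forecast_series(obs_i, ds$registry[i, ], em, seed = 17)
    }))
    v <- run_validation(ds$obs, f, ds$registry,
                        validation_config(lead_days = 2,
                                          modes = "all-hours",
                                          exposures = "shade"))
    mean(v$errors$me)
  })
  expect_true(all(diff(me_by_bias) > 0))
  expect_equal(me_by_bias[1], 0, tolerance = 1e-12)
})
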