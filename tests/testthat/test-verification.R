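# Contingency tables and skill scores against loop-based oracles.

test_that("build_contingency follows the observed-row convention", {
  t <- build_contingency(c(1, 2), c(0, 2))
  m <- unclass(t)
  expect_equal(m[2, 1], 1) # C10: observed 1, predicted 0
  expect_equal(m[3, 3], 1) # C22
  expect_equal(sum(m), 2)
  # identity forecast gives a diagonal table
  obs <- c(0, 1, 2, 3, 1, 2)
  td <- build_contingency(obs, obs)
  expect_equal(unclass(td), diag(c(1, 2, 2, 1)), ignore_attr = TRUE)
  # incomplete pairs are dropped and counted
  tn <- build_contingency(c(1, NA, 2), c(1, 1, NA))
  expect_equal(sum(unclass(tn)), 1)
  expect_equal(attr(tn, "n_dropped"), 2)
  expect_error(build_contingency(c(1, 4), c(0, 0)), "0..3")
  expect_error(build_contingency(1:3, 1:2), "equal length")
})

test_that("contingency counting matches a brute-force pair loop", {
  set.seed(11)
  o <- sample(0:3, 1e4, replace = TRUE, prob = c(0.4, 0.3, 0.25, 0.05))
  p <- sample(0:3, 1e4, replace = TRUE, prob = c(0.35, 0.35, 0.25, 0.05))
  expect_equal(unclass(build_contingency(o, p)), oracle_count_pairs(o, p),
               ignore_attr = TRUE)
})

test_that("every score matches the loop oracle on random tables", {
  tables <- random_tables(1000, seed = 99)
  for (m in tables) {
    t <- as_contingency(m)
    ref <- oracle_scores(m)
    expect_equal(hit_rate(t), ref$hr, tolerance = 1e-9)
    expect_equal(critical_success_index(t), ref$csi, tolerance = 1e-9)
    expect_equal(pod(t, 1), ref$pod1, tolerance = 1e-9)
    expect_equal(pod(t, 2), ref$pod2, tolerance = 1e-9)
    expect_equal(pod(t, 3), ref$pod3, tolerance = 1e-9)
    expect_equal(pod_extended(t, 1), ref$pod1x, tolerance = 1e-9)
    expect_equal(pod_extended(t, 2), ref$pod2x, tolerance = 1e-9)
    expect_equal(lack_alarm(t), ref$na, tolerance = 1e-9)
    expect_equal(false_alarm(t), ref$fa, tolerance = 1e-9)
    expect_equal(normalized_lack_alarm(t), ref$na_star, tolerance = 1e-9)
    expect_equal(normalized_false_alarm(t), ref$fa_star, tolerance = 1e-9)
  }
})

test_that("order relations hold wherever both sides are defined", {
  tables <- random_tables(400, seed = 5, max_count = 6)
  for (m in tables) {
    t <- as_contingency(m)
    s <- skill_scores(t)
    if (!is.na(s$pod1x) && !is.na(s$pod1)) expect_gte(s$pod1x, s$pod1)
    if (!is.na(s$pod2x) && !is.na(s$pod2)) expect_gte(s$pod2x, s$pod2)
    if (!is.na(s$na_star) && !is.na(s$na)) expect_lte(s$na_star, s$na)
    if (!is.na(s$fa_star) && !is.na(s$fa)) expect_lte(s$fa_star, s$fa)
  }
})

test_that("degenerate tables yield undefined scores, never zero", {
  # all pairs correct and in class 0: no events, CSI undefined
  t0 <- as_contingency(diag(c(10, 0, 0, 0)))
  expect_true(is.na(critical_success_index(t0)))
  expect_equal(hit_rate(t0), 100)
  # no observed class 3: POD3 undefined
  expect_true(is.na(pod(t0, 3)))
  # class 0 never predicted: lack alarm undefined, normalized defined
  m <- matrix(0, 4, 4); m[2, 2] <- 5; m[3, 4] <- 5
  t1 <- as_contingency(m)
  expect_true(is.na(lack_alarm(t1)))
  expect_equal(normalized_lack_alarm(t1), 0)
  # class 0 never observed: false alarm undefined
  expect_true(is.na(false_alarm(t1)))
  # empty table: everything undefined
  te <- as_contingency(matrix(0, 4, 4))
  expect_true(all(is.na(unlist(skill_scores(te)[, -1]))))
})

test_that("strict mode reproduces the literal printed formulas", {
  m <- matrix(1:16, 4, 4) # arbitrary distinct counts
  t <- as_contingency(m)
  # literal hit-rate denominator omits the predicted-class-2 column
  expect_equal(hit_rate(t, strict = TRUE),
               100 * sum(diag(m)) / sum(m[, -3]))
  # literal CSI denominator counts C02 twice and lacks C03
  den <- (m[2, 1] + m[3, 1] + m[4, 1]) + sum(m[, 2]) + sum(m[, 3]) +
    m[1, 3] + (m[2, 4] + m[3, 4] + m[4, 4])
  expect_equal(critical_success_index(t, strict = TRUE),
               100 * (m[2, 2] + m[3, 3] + m[4, 4]) / den)
  # extended POD1 variant crediting class-3 forecasts
  expect_equal(pod_extended(t, 1, include_higher = TRUE),
               100 * (m[2, 2] + m[2, 3] + m[2, 4]) / sum(m[2, ]))
  expect_gte(pod_extended(t, 1, include_higher = TRUE), pod_extended(t, 1))
})

test_that("tables merge additively and scores agree with pooled streams", {
  set.seed(3)
  o1 <- sample(0:3, 500, TRUE); p1 <- sample(0:3, 500, TRUE)
  o2 <- sample(0:3, 300, TRUE); p2 <- sample(0:3, 300, TRUE)
  t12 <- build_contingency(o1, p1) + build_contingency(o2, p2)
  tpool <- build_contingency(c(o1, o2), c(p1, p2))
  expect_equal(unclass(t12), unclass(tpool), ignore_attr = TRUE)
  expect_equal(skill_scores(t12), skill_scores(tpool))
})

test_that("class frequencies are normalized marginals", {
  m <- matrix(c(10, 2, 1, 0, 3, 20, 4, 0, 1, 5, 15, 1, 0, 0, 2, 3), 4, 4,
              byrow = TRUE)
  cf <- class_frequencies(as_contingency(m))
  expect_equal(sum(cf$observed_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cf$predicted_pct), 100, tolerance = 1e-9)
  expect_equal(cf$observed_pct, 100 * rowSums(m) / sum(m))
  expect_equal(cf$predicted_pct, 100 * colSums(m) / sum(m))
  # diagonal table: identical marginals
  cfd <- class_frequencies(as_contingency(diag(c(5, 5, 5, 5))))
  expect_equal(cfd$observed_pct, cfd$predicted_pct)
})

test_that("continuous errors follow their definitions", {
  expect_equal(continuous_errors(c(1, 2, 3), c(1, 2, 3))[1:3] |> unlist(),
               c(me = 0, mae = 0, rmse = 0))
  e <- continuous_errors(c(3, 4), c(1, 2))
  expect_equal(unlist(e[1:3]), c(me = 2, mae = 2, rmse = 2))
  # balancing deviations: zero mean error but unit absolute error
  e2 <- continuous_errors(c(1, -1), c(0, 0))
  expect_equal(unlist(e2[1:3]), c(me = 0, mae = 1, rmse = 1))
  # inequality chain on random data
  set.seed(8)
  y <- rnorm(500); o <- rnorm(500)
  e3 <- continuous_errors(y, o)
  expect_gte(e3$mae, abs(e3$me))
  expect_gte(e3$rmse, e3$mae)
  expect_equal(continuous_errors(numeric(0), numeric(0))$n, 0L)
  expect_true(is.na(continuous_errors(NA_real_, 1)$me))
})

test_that("skill_report averages stations within areas and honors exclusions", {
  registry <- tibble::tibble(
    id = c("A1", "A2", "A3", "B1"),
    area = c("A", "A", "A", "B"),
    excluded = c(FALSE, FALSE, TRUE, FALSE)
  )
  # A1: POD2 = 60 (3 of 5); A2: POD2 = 80 (4 of 5); A3 wildly different
  mk <- function(hit, miss) {
    dplyr::bind_rows(
      tibble::tibble(observed_class = rep(2L, hit), predicted_class = 2L),
      tibble::tibble(observed_class = rep(2L, miss), predicted_class = 0L),
      tibble::tibble(observed_class = rep(0L, 5), predicted_class = 0L)
    )
  }
  pairs <- dplyr::bind_rows(
    mk(3, 2) |> dplyr::mutate(station_id = "A1"),
    mk(4, 1) |> dplyr::mutate(station_id = "A2"),
    mk(0, 5) |> dplyr::mutate(station_id = "A3"),
    mk(5, 0) |> dplyr::mutate(station_id = "B1")
  )
  rep_ <- skill_report(pairs, registry)
  areaA <- rep_$areas[rep_$areas$area == "A", ]
  expect_equal(areaA$pod2, 70) # unweighted mean of 60 and 80
  expect_equal(areaA$n_stations, 2) # excluded station never enters
  # the excluded station keeps its per-station row
  expect_true("A3" %in% rep_$stations$station_id)
  # single-station area: area value equals the station value
  areaB <- rep_$areas[rep_$areas$area == "B", ]
  expect_equal(areaB$pod2, 100)
  # undefined per-station scores are omitted from the mean, with a count
  expect_equal(areaA$pod3_n_def, 0)
  expect_true(is.na(areaA$pod3))
  expect_error(skill_report(pairs |> dplyr::mutate(station_id = "ZZ"),
                            registry), "registry")
})

test_that("classified-pair fixtures round-trip through build_contingency", {
  tables <- random_tables(20, seed = 21, max_count = 12)
  for (m in tables) {
    pairs <- generate_classified_pair(m, seed = 4)
    expect_equal(unclass(build_contingency(pairs$observed_class,
                                           pairs$predicted_class)),
                 matrix(as.integer(m), 4, 4), ignore_attr = TRUE)
  }
  # diagonal target: perfect hit rate downstream
  pairs <- generate_classified_pair(diag(c(10, 10, 10, 10)))
  expect_equal(hit_rate(build_contingency(pairs$observed_class,
                                          pairs$predicted_class)), 100)
  # empty observed row 3 propagates as undefined POD3
  m <- diag(c(5, 5, 5, 0))
  pairs <- generate_classified_pair(m)
  expect_true(is.na(pod(build_contingency(pairs$observed_class,
                                          pairs$predicted_class), 3)))
})
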