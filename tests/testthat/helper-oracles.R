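# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package: explicit loops and scalar arithmetic.

# pair-counting loop for the contingency convention (rows observed)
oracle_count_pairs <- function(observed, predicted) {
  m <- matrix(0L, 4, 4)
  for (i in seq_along(observed)) {
    m[observed[i] + 1, predicted[i] + 1] <- m[observed[i] + 1,
                                              predicted[i] + 1] + 1L
  }
  m
}

# every categorical score from a plain 4x4 matrix, cellwise
oracle_scores <- function(m) {
  c00 <- m[1, 1]
  total <- 0
  for (a in 1:4) for (b in 1:4) total <- total + m[a, b]
  sdiag <- m[1, 1] + m[2, 2] + m[3, 3] + m[4, 4]
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  pod_k <- function(k) div(m[k + 1, k + 1], sum(m[k + 1, ]))
  list(
    hr = div(sdiag, total),
    csi = div(m[2, 2] + m[3, 3] + m[4, 4], total - c00),
    pod1 = pod_k(1), pod2 = pod_k(2), pod3 = pod_k(3),
    pod1x = div(m[2, 2] + m[2, 3], sum(m[2, ])),
    pod2x = div(m[3, 3] + m[3, 4], sum(m[3, ])),
    na = div(m[2, 1] + m[3, 1] + m[4, 1],
             m[1, 1] + m[2, 1] + m[3, 1] + m[4, 1]),
    fa = div(m[1, 2] + m[1, 3] + m[1, 4],
             m[1, 1] + m[1, 2] + m[1, 3] + m[1, 4]),
    na_star = div(m[2, 1] + m[3, 1] + m[4, 1], total),
    fa_star = div(m[1, 2] + m[1, 3] + m[1, 4], total)
  )
}

random_tables <- function(n, seed, max_count = 50) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    matrix(sample.int(max_count + 1, 16, replace = TRUE) - 1L, 4, 4)
  })
}

# a tiny identity scenario: small network, zero forecast error
identity_scenario <- function(n = c(A = 1, B = 1, C = 1), days = 10,
                              seed = 7) {
  synthetic_scenario(
    n_stations = n,
    start = as.Date("2019-06-01"),
    end = as.Date("2019-06-01") + days - 1,
    error_model = forecast_error_model(
      noise_sd = c(ta = 0, rh = 0, wind = 0, solar = 0)
    ),
    complex_station = FALSE, elev_offset_sd = 0, seed = seed
  )
}
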