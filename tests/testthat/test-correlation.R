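test_that("mean subtraction forces the pair-summed autocovariance to zero", {
  set.seed(3)
  v <- cumsum(rnorm(40))
  x <- v - mean(v)
  # sum over all ordered pairs (i, j), lag 0 included
  expect_equal(sum(outer(x, x)), 0, tolerance = 1e-9)

  # the same identity on the estimator output: pair-weighted sum of the
  # unnormalised curve over all lags vanishes
  ts <- make_traces(list(v), dt = 6)
  K <- length(v)
  cur <- connected_autocorrelation(ts, max_lag = K - 1)
  w <- ifelse(cur$lag == 0, K, 2 * (K - cur$lag))
  expect_equal(sum(w * cur$value_raw) / sum(abs(cur$value_raw)), 0,
               tolerance = 1e-9)
})

test_that("short traces dig a spurious negative valley", {
  m <- two_state_model(0.06, 0.06)
  long <- simulate_trace_set(m, std_construct, 400, 300, 4, seed = 61)
  short <- simulate_trace_set(m, std_construct, 1200, 60, 4, seed = 62)
  c_long <- connected_autocorrelation(long)
  c_short <- connected_autocorrelation(short)
  expect_lt(min(c_short$value), -0.6)
  expect_gt(min(c_long$value), -0.45)
  expect_lt(min(c_short$value), 2 * min(c_long$value))
})

test_that("equal-length truncation collapses curves from different durations", {
  m <- two_state_model(0.03, 0.03)
  a <- simulate_trace_set(m, std_construct, 500, 360, 6, seed = 63)
  b <- simulate_trace_set(m, std_construct, 500, 120, 6, seed = 64)
  Kb <- length(b$intensity[[1]])
  a_cut <- a
  a_cut$intensity <- lapply(a$intensity, function(v) v[seq_len(Kb)])
  a_cut$time_s <- lapply(a$time_s, function(t) t[seq_len(Kb)])
  a_cut$steady <- lapply(a_cut$intensity, function(v) rep(TRUE, length(v)))
  ca <- connected_autocorrelation(a_cut)
  cb <- connected_autocorrelation(b)
  i <- 2:(Kb - 1)
  z <- abs(ca$value[i] - cb$value[i]) / sqrt(ca$se[i]^2 + cb$se[i]^2)
  expect_lt(max(z), 4)
})

test_that("theoretical curves reduce and mirror as they must", {
  lags <- seq(0, 300, by = 6)
  two <- theoretical_autocorrelation(two_state_model(0.004, 0.011),
                                     std_loops, lags)
  cy1 <- theoretical_autocorrelation(cycle_model(0.011, 0.004),
                                     std_loops, lags)
  expect_equal(cy1$value, two$value, tolerance = 1e-10)

  # Poisson-like curve is the probe autocorrelation only: any firing rate
  # gives the same normalised curve
  p1 <- theoretical_autocorrelation(poisson_model(0.003), std_loops, lags)
  p2 <- theoretical_autocorrelation(poisson_model(0.3), std_loops, lags)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)

  # cross-correlation: identical probes give the autocorrelation back
  xx <- theoretical_cross_correlation(two_state_model(0.01, 0.01),
                                      std_loops, std_loops, lags)
  aa <- theoretical_autocorrelation(two_state_model(0.01, 0.01),
                                    std_loops, lags)
  expect_equal(xx$value, aa$value, tolerance = 1e-12)

  # swapping channels mirrors the lag axis (two probes on one 32-step gene)
  L5 <- build_loop_function(construct_5prime())
  L3 <- build_loop_function(gene_construct(20, 12, 0, 24))
  lags2 <- seq(-180, 180, by = 6)
  ab <- theoretical_cross_correlation(two_state_model(0.01, 0.01),
                                      L5, L3, lags2)
  ba <- theoretical_cross_correlation(two_state_model(0.01, 0.01),
                                      L3, L5, lags2)
  expect_equal(ab$value, rev(ba$value), tolerance = 1e-10)
  expect_gt(ab$lag_s[which.max(ab$value)], 0)  # 3' lags the 5' channel
})

test_that("Poisson-like theory matches simulated uncorrelated firing", {
  pm <- poisson_model(0.02)
  ts <- simulate_trace_set(pm, std_construct, 800, 300, 6, seed = 65)
  emp <- connected_autocorrelation(ts)
  K <- length(ts$intensity[[1]])
  th <- finite_trace_correction(autocovariance_function(pm, std_loops),
                                K, 6, step_time_s = 6)
  i <- 2:(floor(K / 2) + 1)
  z <- abs(emp$value[i] - th$value[i]) / emp$se[i]
  expect_lt(max(z), 3.5)
})

test_that("finite-trace correction recovers the infinite-trace limit", {
  m <- two_state_model(0.01, 0.02)
  f <- autocovariance_function(m, std_loops)
  K <- 3000
  corr <- finite_trace_correction(f, K, 6, step_time_s = 6)
  lags <- seq(0, 300, by = 6)
  inf <- f(lags) / f(6)   # same lag-1 normalisation
  expect_lt(max(abs(corr$value[seq_along(lags)] - inf)), 0.02)

  expect_error(finite_trace_correction(f, 2, 6), "K >= 3")
})

test_that("correction expectation is exact against brute-force averaging", {
  m <- two_state_model(0.06, 0.06)
  ts <- simulate_trace_set(m, std_construct, 3000, 60, 4, seed = 66)
  K <- length(ts$intensity[[1]])
  raw <- raw_mean_subtracted_autocov(ts, K - 1)
  th <- finite_trace_correction(autocovariance_function(m, std_loops),
                                K, 4, step_time_s = 6)
  # compare lag-1-normalised shapes
  expect_lt(max(abs(raw / raw[2] - th$value)), 0.06)
})

test_that("degenerate inputs are rejected or flagged", {
  const <- make_traces(list(rep(2, 20), rep(5, 20)))
  expect_error(connected_autocorrelation(const), "constant")
  mix <- make_traces(list(rep(2, 20), cumsum(rnorm(20))))
  expect_warning(connected_autocorrelation(mix, variance = "per_trace"),
                 "constant trace")
  # pooled mode keeps silent traces in the ensemble
  expect_silent(connected_autocorrelation(mix))
})
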