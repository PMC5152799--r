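test_that("calibration recovers the intensity scale and is equivariant", {
  # an (almost) always-ON promoter saturates the gene: max = I0 * sum(L)
  on <- two_state_model(100, 1e-8)
  ts <- simulate_trace_set(on, std_construct, 5, 300, 6, seed = 71,
                           intensity_per_loop = 17.3)
  cal <- calibrate_traces(ts, std_loops)
  expect_equal(cal$i0, 17.3, tolerance = 1e-10)

  m <- two_state_model(0.01, 0.01)
  ts2 <- simulate_trace_set(m, std_construct, 30, 300, 6, seed = 72)
  cal_a <- calibrate_traces(ts2, std_loops)
  cal_b <- calibrate_traces(scale_traces(ts2, 7), std_loops)
  expect_equal(cal_b$i0, 7 * cal_a$i0)
  expect_equal(cal_b$traces$intensity, cal_a$traces$intensity)

  zero <- make_traces(list(rep(0, 10), rep(0, 10)))
  expect_error(calibrate_traces(zero, std_loops), "calibration impossible")
})

test_that("P_on estimation inverts the mean-fluorescence law", {
  s <- sum(std_loops)
  sat <- make_traces(list(rep(s, 20)))
  expect_equal(estimate_pon(sat, std_loops), 1)
  expect_equal(estimate_pon(make_traces(list(rep(0, 20))), std_loops), 0)
  expect_error(estimate_pon(make_traces(list(rep(2 * s, 20))), std_loops),
               "mis-calibrated")

  # anterior-like kinetics: half-ON occupancy recovered end to end
  m <- two_state_model(0.015, 0.015)
  ts <- simulate_trace_set(m, std_construct, 200, 600, 6, seed = 73,
                           intensity_per_loop = 11)
  cal <- calibrate_traces(ts, std_loops)
  expect_lt(abs(estimate_pon(cal$traces, std_loops) - 0.5), 0.05)
})

test_that("rate fit recovers the switching timescale", {
  m <- two_state_model(0.01, 0.01)
  ts <- simulate_trace_set(m, std_construct, 200, 600, 6, seed = 74,
                           intensity_per_loop = 5)
  res <- infer_kinetics(ts, "two_state", std_construct)
  expect_lt(abs(res$k_sum - 0.02) / 0.02, 0.15)
  expect_equal(res$rates$k_on + res$rates$k_off, res$k_sum)
  expect_equal(res$i0, 5, tolerance = 0.15 * 5)

  # P_on (and the whole inference) is invariant under intensity rescaling
  res_scaled <- infer_kinetics(scale_traces(ts, 40), "two_state",
                               std_construct)
  expect_equal(res_scaled$p_on, res$p_on)
  expect_equal(res_scaled$k_sum, res$k_sum)
})

test_that("objective prefers the truth over a 2x-perturbed rate sum", {
  m <- two_state_model(0.01, 0.01)
  ts <- simulate_trace_set(m, std_construct, 300, 600, 6, seed = 75)
  res <- fit_rates(ts, "two_state", std_construct, p_on = 0.5)
  L <- std_loops
  emp <- res$empirical
  obj <- function(ks)
    msburst:::fit_objective(two_state_model(ks / 2, ks / 2), emp, res$K,
                            res$dt_s, 6, res$fit_lags, L)
  expect_lt(obj(0.02), obj(0.04))
  expect_lt(obj(0.02), obj(0.01))
})

test_that("Poisson-like fits only rival two-state fits for fast switching", {
  fast <- simulate_trace_set(two_state_model(0.012, 0.108), std_construct,
                             400, 360, 6, seed = 76)
  slow <- simulate_trace_set(two_state_model(0.002, 0.018), std_construct,
                             400, 360, 6, seed = 77)
  mse <- function(ts, fam) {
    cal <- calibrate_traces(ts, std_loops)
    p <- estimate_pon(cal$traces, std_loops)
    suppressWarnings(fit_rates(cal$traces, fam, std_construct,
                               p_on = p)$mse)
  }
  rel_fast <- mse(fast, "poisson") / mse(fast, "two_state")
  rel_slow <- mse(slow, "poisson") / mse(slow, "two_state")
  expect_gt(rel_slow, rel_fast)
  expect_gt(rel_slow, 3)  # slow switching clearly rejects the static promoter
})

test_that("resampling SDs are reproducible and vanish for identical traces", {
  m <- two_state_model(0.01, 0.01)
  one <- simulate_trace_set(m, std_construct, 1, 600, 6, seed = 78)
  dup <- trace_set(rep(one$intensity, 20), rep(one$time_s, 20))
  sd_dup <- resample_uncertainty(dup, "two_state", std_construct,
                                 n_subsets = 6, seed = 1)
  expect_lt(sd_dup$k_sum, 1e-10)
  expect_lt(sd_dup$p_on, 1e-12)

  ts <- simulate_trace_set(m, std_construct, 40, 600, 6, seed = 79)
  s1 <- resample_uncertainty(ts, "two_state", std_construct,
                             n_subsets = 6, seed = 3)
  s2 <- resample_uncertainty(ts, "two_state", std_construct,
                             n_subsets = 6, seed = 3)
  expect_identical(s1, s2)
  expect_gt(s1$k_sum, 0)
  expect_error(resample_uncertainty(subset_traces(ts, idx = 1:5),
                                    "two_state", std_construct),
               "at least 10")
})

test_that("resampling SD brackets the true parameter most of the time", {
  m <- two_state_model(0.01, 0.01)
  hits <- 0
  for (i in 1:5) {
    ts <- simulate_trace_set(m, std_construct, 60, 600, 6, seed = 80 + i)
    fit <- infer_kinetics(ts, "two_state", std_construct, n_subsets = 8,
                          seed = i)
    if (abs(fit$k_sum - 0.02) <= 2 * fit$sd$k_sum) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("cycle fit flags the OFF-rate ratio of the generating model", {
  # strongly non-exponential OFF times, long traces: ratio near 1
  cyc <- cycle_model(0.018, c(0.004, 0.004))
  ts <- simulate_trace_set(cyc, std_construct, 120, 1800, 6, seed = 85)
  d <- discriminate_cycle_vs_two_state(ts, std_construct)
  expect_gte(d$ratio, 0.5)
  expect_identical(d$classification, "cycle")
  expect_lt(abs(d$k_sum - 0.02) / 0.02, 0.35)
})
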