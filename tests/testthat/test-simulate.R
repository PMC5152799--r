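test_that("simulation is reproducible under a fixed seed", {
  m <- two_state_model(0.01, 0.02)
  x1 <- simulate_promoter_trace(m, 600, seed = 5)
  x2 <- simulate_promoter_trace(m, 600, seed = 5)
  x3 <- simulate_promoter_trace(m, 600, seed = 6)
  expect_identical(x1, x2)
  expect_false(identical(x1, x3))

  ts1 <- simulate_trace_set(m, std_construct, 5, 300, 6, seed = 9)
  ts2 <- simulate_trace_set(m, std_construct, 5, 300, 6, seed = 9)
  expect_identical(ts1$intensity, ts2$intensity)
})

test_that("occupancy and dwell-time statistics match the model", {
  m <- two_state_model(0.01, 0.01)
  x <- simulate_promoter_trace(m, 3e4 * 6, step_time_s = 6, seed = 21)
  # law of large numbers for the ON fraction
  tau_steps <- 1 / (0.02 * 6)
  se <- sqrt(2 * tau_steps * 0.25 / length(x))
  expect_lt(abs(mean(x) - 0.5), 4 * se)

  # ON dwells are exponential with mean 1/k_off (fine grid, jitter breaks
  # the discretisation ties for the KS test)
  m2 <- two_state_model(0.02, 0.01)
  x2 <- simulate_promoter_trace(m2, 4e5, step_time_s = 0.5, seed = 22)
  runs <- rle(as.vector(x2))
  on_dwell <- runs$lengths[runs$values == 1] * 0.5
  on_dwell <- on_dwell[-c(1, length(on_dwell))]
  expect_gt(length(on_dwell), 1000)
  expect_equal(mean(on_dwell), 100, tolerance = 0.1)
  set.seed(1)
  jit <- on_dwell + stats::runif(length(on_dwell), -0.25, 0.25)
  expect_gt(stats::ks.test(jit, "pexp", 0.01)$p.value, 0.01)

  # cycle OFF dwells are hypoexponential: mean is the sum of stage means
  cy <- cycle_model(0.02, c(0.02, 0.04))
  x3 <- simulate_promoter_trace(cy, 4e5, step_time_s = 0.5, seed = 23)
  runs3 <- rle(as.vector(x3))
  off_dwell <- runs3$lengths[runs3$values == 0] * 0.5
  off_dwell <- off_dwell[-c(1, length(off_dwell))]
  expect_equal(mean(off_dwell), 75, tolerance = 0.12)
  # hypoexponential CV < 1 distinguishes it from a single exponential
  expect_lt(stats::sd(off_dwell) / mean(off_dwell), 0.95)
})

test_that("trace sets respect the fluorescence bounds and the mean law", {
  m <- two_state_model(0.01, 0.01)
  ts <- simulate_trace_set(m, std_construct, 400, 300, 6, seed = 31)
  v <- unlist(ts$intensity)
  expect_true(all(v >= 0 & v <= sum(std_loops)))
  mu <- vapply(ts$intensity, mean, numeric(1))
  sem <- stats::sd(mu) / sqrt(length(mu))
  expect_lt(abs(mean(mu) - mean_fluorescence(0.5, std_loops)), 3 * sem)
})

test_that("oversampling below the step time duplicates steps", {
  m <- two_state_model(0.01, 0.01)
  ts <- simulate_trace_set(m, std_construct, 3, 120, 2, seed = 8)
  v <- ts$intensity[[1]]
  # with dt = 2 s and 6 s steps, nearest-step lookup groups samples
  # k = 2,3,4 then 5,6,7 ... onto one step each
  expect_true(all(v[seq(3, 57, by = 3)] == v[seq(4, 58, by = 3)]))
  expect_true(all(v[seq(4, 58, by = 3)] == v[seq(5, 59, by = 3)]))
})

test_that("two seeds give compatible autocorrelations but different traces", {
  m <- two_state_model(0.02, 0.02)
  a <- simulate_trace_set(m, std_construct, 400, 300, 6, seed = 41)
  b <- simulate_trace_set(m, std_construct, 400, 300, 6, seed = 42)
  expect_false(identical(a$intensity, b$intensity))
  ca <- connected_autocorrelation(a)
  cb <- connected_autocorrelation(b)
  i <- 2:20
  z <- abs(ca$value[i] - cb$value[i]) / sqrt(ca$se[i]^2 + cb$se[i]^2)
  expect_lt(max(z), 3.8)
})

test_that("two-colour channels share one promoter realisation", {
  m <- two_state_model(0.01, 0.01)
  tc <- simulate_two_color(m, construct_5prime(), construct_3prime(),
                           120, 600, 6, seed = 51)
  # identical constructs: the two channels coincide exactly
  tc_same <- simulate_two_color(m, construct_3prime(), construct_3prime(),
                                5, 300, 6, seed = 52)
  expect_identical(tc_same$a$intensity, tc_same$b$intensity)

  # 5' signal leads the 3' signal: cross-correlation peak at positive lag
  cc <- empirical_cross_correlation(tc$a, tc$b, max_lag = 30)
  expect_gt(cc$lag[which.max(cc$value)], 0)

  # an always-ON promoter saturates both channels
  on <- two_state_model(100, 1e-8)
  tc_on <- simulate_two_color(on, construct_5prime(), construct_3prime(),
                              2, 120, 6, seed = 53)
  expect_true(all(unlist(tc_on$a$intensity) == sum(build_loop_function(
    construct_5prime()))))
  expect_true(all(unlist(tc_on$b$intensity) == sum(std_loops)))
})
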