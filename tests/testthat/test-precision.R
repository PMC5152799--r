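test_that("closed-form relative errors evaluate and scale correctly", {
  # anterior-like kinetics: tau_i = 33 s, P_on = 0.5, T = 240 s
  e <- relative_error_two_state(1 / 66, 1 / 66, 240)
  expect_equal(e$rel_error, sqrt(2 * 33 * 0.5 / (240 * 0.5)))
  expect_equal(e$rel_error, 0.5244, tolerance = 1e-4)

  # T -> Inf and P_on -> 1 kill the error
  expect_lt(relative_error_two_state(1 / 66, 1 / 66, 1e9)$rel_error, 1e-3)
  expect_lt(relative_error_two_state(1, 1e-9, 240)$rel_error, 1e-4)

  ep <- relative_error_poisson(240, 6, p_on = 0.1)
  expect_equal(ep$rel_error, 0.15)
  expect_equal(relative_error_poisson(240, 6, p_on = 1)$rel_error, 0)
  expect_equal(relative_error_poisson(240, 6, p_on = 0.5)$rel_error,
               0.1118, tolerance = 1e-4)
  # supplying the firing rate instead of the occupancy is equivalent
  r <- 0.1 / (6 * 0.9)
  expect_equal(relative_error_poisson(240, 6, firing_rate = r)$rel_error,
               0.15, tolerance = 1e-12)

  # T^(-1/2) scaling
  expect_equal(relative_error_two_state(0.01, 0.01, 400)$rel_error /
                 relative_error_two_state(0.01, 0.01, 1600)$rel_error, 2)
  expect_equal(relative_error_poisson(400, p_on = 0.2)$rel_error /
                 relative_error_poisson(1600, p_on = 0.2)$rel_error, 2)
})

test_that("Monte-Carlo occupancy error converges to the two-state formula", {
  m <- two_state_model(0.02, 0.02)   # tau_i = 25 s
  mc <- relative_error_monte_carlo(m, 1000, n_realizations = 1500,
                                   step_time_s = 5, seed = 91)
  th <- relative_error_two_state(0.02, 0.02, 1000)
  expect_lt(abs(mc$rel_error - th$rel_error) / th$rel_error, 0.1)
  expect_warning(relative_error_monte_carlo(m, 100, n_realizations = 50,
                                            seed = 1),
                 "fewer than 100")
})

test_that("promoter architectures order by readout precision", {
  for (koff in c(0.01, 0.02)) {
    for (koneff in c(0.005, 0.01)) {
      two <- relative_error_monte_carlo(two_state_model(koneff, koff), 600,
                                        400, step_time_s = 3, seed = 92)
      cyc <- relative_error_monte_carlo(
        cycle_model(koff, c(2 * koneff, 2 * koneff)), 600, 400,
        step_time_s = 3, seed = 93)
      expect_lt(cyc$rel_error, two$rel_error)
    }
  }
  # Poisson-like beats the two-state promoter at equal occupancy
  for (p in c(0.1, 0.3, 0.5, 0.8)) {
    for (kon in c(0.01, 0.03)) {
      e2 <- relative_error_two_state(kon, kon * (1 - p) / p, 240)$rel_error
      ep <- relative_error_poisson(240, 6, p_on = p)$rel_error
      expect_lt(ep, e2)
    }
  }
})

test_that("empirical relative error behaves per spatial bin", {
  # identical deterministic traces: zero variability
  v <- rep(list(c(1, 2, 3, 2, 1) * 10), 8)
  ts <- make_traces(v, dt = 6, ap_position = rep(0.22, 8))
  pe <- empirical_relative_error(ts)
  expect_equal(pe$rel_error, 0)

  # simulated two-state ensemble reproduces the independent-measurement law
  m <- two_state_model(0.015, 0.015)
  sim <- simulate_trace_set(m, std_construct, 400, 600, 6, seed = 94)
  sim$meta$ap_position <- rep(0.2, 400)
  cal <- calibrate_traces(sim, std_loops)
  pe2 <- empirical_relative_error(cal$traces)
  th <- relative_error_two_state(0.015, 0.015, 600)
  expect_lt(abs(pe2$rel_error - th$rel_error) / th$rel_error, 0.2)

  # binary activity in a high-occupancy region: every nucleus fires
  pb <- empirical_relative_error(cal$traces, statistic = "binary")
  expect_equal(pb$rel_error, 0)

  # small bins are excluded with a warning
  ts_small <- make_traces(v[1:2], dt = 6, ap_position = c(0.1, 0.9))
  expect_warning(empirical_relative_error(ts_small), "bin")
})

test_that("lineage integration pools independent cycles", {
  m <- two_state_model(0.003, 0.027)  # boundary-like occupancy
  base <- function(seed) simulate_trace_set(m, std_construct, 60, 300, 6,
                                            seed = seed)
  set.seed(42)
  cyc_sets <- lapply(1:3, function(ci) base(100 + ci))
  intensity <- do.call(c, lapply(cyc_sets, function(s) s$intensity))
  time_s <- do.call(c, lapply(cyc_sets, function(s) s$time_s))
  meta <- data.frame(
    embryo_id = 1, cycle = rep(11:13, each = 60),
    nucleus_id = c(1:60, 1:60, 1:60),
    ap_position = rep(runif(60, 0.45, 0.55), 3),
    # nucleus n descends from nucleus ceiling(n/2)-like links; here nuclei
    # map 1:1 across cycles, which is a valid lineage for the estimator
    mother_id = c(rep(NA, 60), 1:60, 1:60))
  ts <- trace_set(intensity, time_s, meta)

  single <- empirical_relative_error(subset_traces(ts, cycle = 13),
                                     statistic = "total", bin_width = 0.2)
  pooled <- lineage_integrated_error(ts, bin_width = 0.2)
  expect_lt(pooled$rel_error, single$rel_error)
  # weights 1 + 1/2 + 1/4: variance of the weighted sum of iid cycles
  # predicts the error ratio sqrt(1 + 1/4 + 1/16) / (1 + 1/2 + 1/4)
  expect_equal(pooled$rel_error / single$rel_error,
               sqrt(1 + 1 / 4 + 1 / 16) / 1.75, tolerance = 0.25)

  # zero-intensity ancestors change nothing
  ts0 <- ts
  for (i in which(meta$cycle %in% 11:12))
    ts0$intensity[[i]] <- ts0$intensity[[i]] * 0
  z <- lineage_integrated_error(ts0, bin_width = 0.2)
  s13 <- empirical_relative_error(subset_traces(ts0, cycle = 13),
                                  statistic = "total", bin_width = 0.2)
  expect_equal(z$rel_error, s13$rel_error, tolerance = 1e-12)

  # broken links are skipped and counted
  tsb <- ts
  tsb$meta$mother_id[tsb$meta$cycle == 13][1:5] <- 999
  expect_warning(out <- lineage_integrated_error(tsb, bin_width = 0.2),
                 "broken lineage")
  expect_equal(attr(out, "skipped"), 5L)
})

test_that("integration time scales as the squared error ratio", {
  expect_equal(integration_time_factor(0.5, 0.1), 25)
  expect_equal(integration_time_factor(0.3, 0.3), 1)
  expect_equal(integration_time_factor(1.5, 0.1), 225)
  expect_lt(integration_time_factor(0.05, 0.1), 1)
})
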