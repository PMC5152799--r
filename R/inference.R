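#' Calibrate raw intensities to loop units
#'
#' The measured intensity is `I(t) = I0 * F(t)` with an unknown intensity per
#' fluorescing MS2 loop `I0`. The saturation intensity is estimated as the
#' mean over traces of each trace's maximum (more robust than the absolute
#' maximum over all traces), so `I0 = <max_t I(t)> / sum_i L_i` and the
#' calibrated signal is `F(t) = I(t) / I0`.
#'
#' @param traces A [trace_set()] (raw intensities).
#' @param loop_fn Loop function of the construct.
#' @return List with `i0` (intensity units per loop) and `traces`, the
#'   calibrated set in loop units.
#' @export
calibrate_traces <- function(traces, loop_fn) {
  vs <- steady_values(traces)
  mx <- vapply(vs, function(v) if (length(v)) max(v) else -Inf, numeric(1))
  mx <- mx[is.finite(mx)]
  if (!length(mx) || all(mx <= 0))
    stop("calibration impossible: no trace with a positive sample")
  i0 <- mean(mx) / sum(as.numeric(loop_fn))
  list(i0 = i0, traces = scale_traces(traces, 1 / i0))
}

#' Estimate the stationary ON probability from calibrated traces
#'
#' Time-and-ensemble mean of the calibrated fluorescence over the
#' steady-state windows, divided by the saturation level `sum_i L_i`
#' (inversion of the mean-fluorescence relation).
#'
#' @param traces Calibrated [trace_set()] (loop units).
#' @param loop_fn Loop function.
#' @return Estimated `P_on` in `[0, 1]`.
#' @export
estimate_pon <- function(traces, loop_fn) {
  vs <- steady_values(traces)
  p <- mean(unlist(vs)) / sum(as.numeric(loop_fn))
  if (p > 1)
    stop("estimated P_on > 1: traces appear mis-calibrated")
  max(p, 0)
}

# Free-scale -> promoter model, with the rate ratio pinned by P_on (Step 2).
model_from_scale <- function(family, scale, p_on, extra = NULL) {
  switch(family,
    two_state = two_state_model(k_on = p_on * scale,
                                k_off = (1 - p_on) * scale),
    cycle = {
      rho <- extra$ratio              # k_1 / k_2 in (0, 1]
      kon_eff <- p_on * scale
      k_off <- (1 - p_on) * scale
      k2 <- kon_eff * (1 + rho) / rho
      k1 <- kon_eff * (1 + rho)
      cycle_model(k_off, c(k1, k2))
    },
    gamma = {
      alpha <- extra$alpha
      k_off <- (1 - p_on) * scale
      beta <- alpha * k_off * p_on / (1 - p_on)
      gamma_model(k_off, alpha, beta)
    },
    stop("unsupported family: ", family))
}

# Pair-count-weighted MSE between empirical curve and the corrected model
# curve (both normalised at lag 1) over the fit lag range.
fit_objective <- function(model, emp, K, dt, step_time_s, fit_lags, loop_fn) {
  th <- finite_trace_correction(autocovariance_function(model, loop_fn,
                                                        step_time_s = step_time_s),
                                K = K, dt_s = dt, step_time_s = step_time_s)
  i <- fit_lags + 1L
  w <- emp$pair_count[i]
  sum(w * (emp$value[i] - th$value[i])^2) / sum(w)
}

# Log-spaced scan + golden-section refinement of a 1-D objective.
scan_golden <- function(fn, lower, upper, n_grid = 25, tol = 1e-3) {
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  vals <- vapply(grid, fn, numeric(1))
  b <- which.min(vals)
  at_boundary <- b == 1 || b == n_grid
  lo <- grid[max(b - 1, 1)]; hi <- grid[min(b + 1, n_grid)]
  opt <- stats::optimize(fn, lower = lo, upper = hi, tol = tol * grid[b])
  flat <- (max(vals) - min(vals)) < 1e-10 * max(abs(vals), 1e-30)
  list(minimum = opt$minimum, objective = opt$objective,
       at_boundary = at_boundary, flat = flat)
}

#' Fit promoter switching rates to the autocorrelation of a trace set
#'
#' Step 3 of the inference: with the rate ratio fixed by `P_on`, the
#' remaining free timescale is found by minimising the pair-count-weighted
#' mean squared error between the empirical connected autocorrelation
#' (lags >= 1) and the finite-trace-corrected model curve. Free parameters:
#' the rate sum `k_on + k_off` (two-state); the effective sum
#' `k_on_eff + k_off` plus the OFF-rate ratio `k_1/k_2` (cycle); `k_off`
#' at each shape on a small `alpha` grid (Gamma). The Poisson-like promoter
#' is fully determined by `P_on` and needs no fit.
#'
#' Traces are truncated to a common steady-state length `K` (the shortest
#' window) so a single finite-trace correction applies. Fit lags run from 1
#' to `min(K - 2, 3 * buffering lags)`: beyond a few buffering times the
#' curve is noise-dominated, and the pair-count weights already downweight
#' large lags.
#'
#' @param traces Calibrated [trace_set()].
#' @param family `"two_state"`, `"cycle"`, `"gamma"` or `"poisson"`.
#' @param construct The [gene_construct()] of the reporter.
#' @param p_on Stationary ON probability (from [estimate_pon()]); estimated
#'   from the traces when `NULL`.
#' @param rate_bounds Bounds (1/s) for the free rate-sum scan.
#' @param alpha_grid Shapes tried for the Gamma family.
#' @param ratio_grid `k_1/k_2` values tried for the cycle family.
#' @param fit_lag_max Optional cap on the largest fit lag (samples).
#' @param variance Variance convention passed to
#'   [connected_autocorrelation()].
#' @return An `inference_result` list: `family`, `p_on`, `rates`, `k_sum`
#'   (fitted `k_on_eff + k_off`), `mse`, `fit` diagnostics, the empirical
#'   and fitted curves.
#' @export
fit_rates <- function(traces, family = c("two_state", "cycle", "gamma",
                                         "poisson"),
                      construct, p_on = NULL,
                      rate_bounds = c(1e-4, 1),
                      alpha_grid = c(1, 1.5, 2, 2.5, 3),
                      ratio_grid = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5,
                                     0.75, 1),
                      fit_lag_max = NULL,
                      variance = "pooled") {
  family <- match.arg(family)
  loop_fn <- build_loop_function(construct)
  step_time_s <- construct$step_time_s
  if (is.null(p_on)) p_on <- estimate_pon(traces, loop_fn)
  if (p_on <= 0 || p_on >= 1)
    stop("P_on = ", signif(p_on, 3), " leaves no free rate ratio to fit")
  if (!all(unlist(lapply(traces$steady, any))))
    stop("traces without a steady-state window; run select_steady_state first")
  dt <- common_dt(traces)
  # common window length so one finite-trace correction applies
  K <- min(lengths(steady_values(traces)))
  if (K < 4) stop("steady-state windows too short to fit (K < 4)")
  tr_cut <- traces
  tr_cut$intensity <- mapply(function(v, s) v[which(s)[seq_len(K)]],
                             traces$intensity, traces$steady,
                             SIMPLIFY = FALSE)
  tr_cut$time_s <- lapply(traces$time_s, function(t) t[seq_len(K)])
  tr_cut$steady <- rep(list(rep(TRUE, K)), n_traces(traces))
  emp <- connected_autocorrelation(tr_cut, max_lag = K - 2L,
                                   variance = variance)
  buff_lags <- max(1L, ceiling(buffering_time(construct) / dt))
  lag_hi <- min(K - 2L, 3L * buff_lags, fit_lag_max %||% Inf)
  fit_lags <- seq_len(lag_hi)
  obj <- function(scale, extra = NULL)
    fit_objective(model_from_scale(family, scale, p_on, extra),
                  emp, K, dt, step_time_s, fit_lags, loop_fn)
  warn <- character(0)
  if (family == "poisson") {
    # r from P_on = tau_block / (tau_block + 1/r)
    r <- p_on / (step_time_s * (1 - p_on))
    model <- poisson_model(r, tau_block = step_time_s)
    mse <- fit_objective(model, emp, K, dt, step_time_s, fit_lags, loop_fn)
    res <- list(rates = list(firing_rate = r), k_sum = NA_real_, mse = mse,
                model = model)
  } else if (family == "two_state") {
    sg <- scan_golden(obj, rate_bounds[1], rate_bounds[2])
    model <- model_from_scale(family, sg$minimum, p_on)
    res <- list(rates = list(k_on = model$k_on, k_off = model$k_off),
                k_sum = sg$minimum, mse = sg$objective, model = model,
                at_boundary = sg$at_boundary, flat = sg$flat)
    if (sg$at_boundary) warn <- c(warn, "rate fit at scan boundary")
    if (sg$flat) warn <- c(warn, "objective is flat; fit is degenerate")
  } else if (family == "cycle") {
    best <- NULL
    for (rho in ratio_grid) {
      sg <- scan_golden(function(s) obj(s, list(ratio = rho)),
                        rate_bounds[1], rate_bounds[2])
      if (is.null(best) || sg$objective < best$objective)
        best <- c(sg, list(ratio = rho))
    }
    model <- model_from_scale(family, best$minimum, p_on,
                              list(ratio = best$ratio))
    res <- list(rates = list(k_off = model$k_off,
                             k_1 = model$off_rates[1],
                             k_2 = model$off_rates[2],
                             ratio = best$ratio),
                k_sum = best$minimum, mse = best$objective, model = model,
                at_boundary = best$at_boundary, flat = best$flat)
    if (best$at_boundary) warn <- c(warn, "rate fit at scan boundary")
  } else { # gamma
    best <- NULL
    for (alpha in alpha_grid) {
      sg <- scan_golden(function(s) obj(s, list(alpha = alpha)),
                        rate_bounds[1], rate_bounds[2])
      if (is.null(best) || sg$objective < best$objective)
        best <- c(sg, list(alpha = alpha))
    }
    model <- model_from_scale(family, best$minimum, p_on,
                              list(alpha = best$alpha))
    res <- list(rates = list(k_off = model$k_off, alpha = model$alpha,
                             beta = model$beta),
                k_sum = best$minimum, mse = best$objective, model = model,
                at_boundary = best$at_boundary, flat = best$flat)
    if (best$at_boundary) warn <- c(warn, "rate fit at scan boundary")
  }
  for (w in warn) warning(w)
  fitted <- finite_trace_correction(
    autocovariance_function(res$model, loop_fn, step_time_s = step_time_s),
    K = K, dt_s = dt, step_time_s = step_time_s)
  structure(c(list(family = family, p_on = p_on, K = K, dt_s = dt,
                   fit_lags = fit_lags, empirical = emp, fitted = fitted,
                   warnings = warn), res),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("inference_result <", x$family, ">\n", sep = "")
  cat(sprintf("  P_on = %.3g", x$p_on))
  if (!is.na(x$k_sum)) cat(sprintf(", k_sum = %.4g /s", x$k_sum))
  cat("\n  rates:", paste(names(x$rates), signif(unlist(x$rates), 4),
                          sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  fit MSE = %.3g over lags 1..%d (K = %d, dt = %g s)\n",
              x$mse, max(x$fit_lags), x$K, x$dt_s))
  if (!is.null(x$sd) && length(x$sd))
    cat("  resampling SD:", paste(names(x$sd), signif(unlist(x$sd), 3),
                                  sep = " = ", collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Full three-step inference on raw traces
#'
#' Calibration (`I0`), occupancy (`P_on`), rate fit, and optionally
#' subset-resampling uncertainties.
#'
#' @inheritParams fit_rates
#' @param n_subsets Number of resampling subsets (0 skips resampling).
#' @param fraction Fraction of traces per subset.
#' @param seed Seed for the resampling draws.
#' @param ... Passed to [fit_rates()].
#' @return An `inference_result` with `i0` and (if resampled) per-parameter
#'   `sd`.
#' @export
infer_kinetics <- function(traces, family = "two_state", construct,
                           n_subsets = 0, fraction = 0.6, seed = NULL, ...) {
  loop_fn <- build_loop_function(construct)
  cal <- calibrate_traces(traces, loop_fn)
  p_on <- estimate_pon(cal$traces, loop_fn)
  res <- fit_rates(cal$traces, family = family, construct = construct,
                   p_on = p_on, ...)
  res$i0 <- cal$i0
  if (n_subsets > 0) {
    res$sd <- resample_uncertainty(traces, family = family,
                                   construct = construct,
                                   fraction = fraction,
                                   n_subsets = n_subsets, seed = seed, ...)
    res$n_subsets <- n_subsets
  }
  res
}

#' Subset-resampling uncertainties for the inferred parameters
#'
#' Repeats the full inference (calibration included) on random subsets of
#' the traces (default 20 subsets of 60% of the data) and reports the SD of
#' each parameter across subsets.
#'
#' @inheritParams fit_rates
#' @param fraction Fraction of traces in each subset.
#' @param n_subsets Number of subsets.
#' @param seed Seed making the subset draws reproducible.
#' @param ... Passed to [fit_rates()].
#' @return Named list of SDs (`p_on`, `k_sum`, and the family's rates).
#' @export
resample_uncertainty <- function(traces, family = "two_state", construct,
                                 fraction = 0.6, n_subsets = 20,
                                 seed = NULL, ...) {
  M <- n_traces(traces)
  if (M < 10) stop("resampling needs at least 10 traces")
  m_sub <- max(2L, round(fraction * M))
  loop_fn <- build_loop_function(construct)
  picks <- with_seed(seed, replicate(n_subsets, sample.int(M, m_sub),
                                     simplify = FALSE))
  fits <- lapply(picks, function(ix) {
    sub <- subset_traces(traces, idx = ix)
    cal <- calibrate_traces(sub, loop_fn)
    p <- estimate_pon(cal$traces, loop_fn)
    suppressWarnings(fit_rates(cal$traces, family = family,
                               construct = construct, p_on = p, ...))
  })
  pars <- lapply(fits, function(f)
    c(p_on = f$p_on, k_sum = f$k_sum, unlist(f$rates)))
  pm <- do.call(rbind, pars)
  as.list(apply(pm, 2, stats::sd))
}

#' Two-state vs three-state discrimination from the OFF-rate ratio
#'
#' Fits the three-state cycle model and reports the canonicalised ratio
#' `k_1/k_2` of the two OFF-exit rates: a ratio near 0 means one OFF step is
#' effectively instantaneous (a two-state promoter), a ratio near 1 means
#' two comparable OFF steps (a genuine cycle). The classification threshold
#' is 0.5.
#'
#' @inheritParams fit_rates
#' @param ... Passed to [fit_rates()].
#' @return List with `ratio` (in `[0, 1]`), `classification`
#'   (`"two_state"` or `"cycle"`), `k_sum` (`k_on_eff + k_off`) and the
#'   underlying `inference_result`.
#' @export
discriminate_cycle_vs_two_state <- function(traces, construct, ...) {
  loop_fn <- build_loop_function(construct)
  cal <- calibrate_traces(traces, loop_fn)
  p <- estimate_pon(cal$traces, loop_fn)
  fit <- suppressWarnings(fit_rates(cal$traces, family = "cycle",
                                    construct = construct, p_on = p, ...))
  ratio <- fit$rates$ratio
  list(ratio = ratio,
       classification = if (ratio < 0.5) "two_state" else "cycle",
       k_sum = fit$k_sum, fit = fit)
}

#' Repeated model-discrimination experiment on simulated data
#'
#' Simulates `n_repeats` independent trace sets from a ground-truth promoter
#' model and runs [discriminate_cycle_vs_two_state()] on each: the
#' distribution of inferred `k_1/k_2` ratios shows how reliably trace length
#' and nucleus count identify the model class.
#'
#' @param truth A `promoter_model` (two-state or cycle).
#' @param construct A [gene_construct()].
#' @param n_nuclei Traces per repeat.
#' @param duration_s Trace duration (s).
#' @param dt_s Sampling interval (s).
#' @param n_repeats Number of independent repeats.
#' @param seed Master seed.
#' @param ... Passed to the cycle fit.
#' @return Data frame with one row per repeat: `ratio`, `k_sum`,
#'   `classification`.
#' @export
discrimination_experiment <- function(truth, construct, n_nuclei, duration_s,
                                      dt_s, n_repeats = 50, seed = NULL,
                                      ...) {
  seeds <- spawn_seeds(seed, n_repeats)
  rows <- lapply(seq_len(n_repeats), function(i) {
    ts <- simulate_trace_set(truth, construct, n_nuclei, duration_s, dt_s,
                             seed = seeds[i])
    d <- discriminate_cycle_vs_two_state(ts, construct, ...)
    data.frame(repeat_id = i, ratio = d$ratio, k_sum = d$k_sum,
               classification = d$classification)
  })
  do.call(rbind, rows)
}
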