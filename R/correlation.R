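#' Empirical connected autocorrelation of a trace set
#'
#' For each trace the empirical mean is subtracted and the autocovariance at
#' lag `r` samples is computed with the decreasing pair count compensated
#' (`1/(K-r)` per pair). The per-trace curves are combined over traces and
#' the averaged curve is normalised to 1 at the second time point (lag 1):
#' the lag-0 point carries all temporally uncorrelated noise (shot noise,
#' free fluorophore fluctuations) and is never used downstream.
#'
#' Two variance conventions are offered. `"pooled"` (default) divides the
#' trace-averaged autocovariance by the trace-averaged variance; this is the
#' estimator whose expectation [finite_trace_correction()] computes exactly
#' (the constant-denominator replacement used when deriving the finite-trace
#' correction), and all-OFF traces contribute their zeros without any
#' exclusion. `"per_trace"` divides each trace's curve by that trace's own
#' empirical variance before averaging, which additionally cancels
#' nucleus-to-nucleus intensity scale differences in uncalibrated data, at
#' the cost of a small ratio bias for short traces; constant traces are then
#' dropped with a warning.
#'
#' Only the steady-state window of each trace is used.
#'
#' @param traces A [trace_set()] with a common sampling interval.
#' @param max_lag Largest lag in samples (default: longest trace minus 2).
#' @param variance `"pooled"` or `"per_trace"` (see Details).
#' @return A data frame of class `correlation_curve` with columns `lag`
#'   (samples), `lag_s`, `value` (normalised at lag 1), `value_raw`
#'   (normalised by the variance, i.e. 1 at lag 0 in expectation),
#'   `pair_count` (summed `K - r` over traces) and `se` (across-trace
#'   standard error on `value`).
#' @export
connected_autocorrelation <- function(traces, max_lag = NULL,
                                      variance = c("pooled", "per_trace")) {
  variance <- match.arg(variance)
  dt <- common_dt(traces)
  vs <- steady_values(traces)
  vs <- vs[lengths(vs) >= 2]
  if (!length(vs)) stop("need at least 2 time points per trace")
  vars <- vapply(vs, function(v) mean((v - mean(v))^2), numeric(1))
  if (all(vars == 0)) stop("all traces are constant; no correlation signal")
  if (variance == "per_trace" && any(vars == 0)) {
    warning(sum(vars == 0),
            " constant trace(s) excluded from the autocorrelation")
    vs <- vs[vars > 0]
    vars <- vars[vars > 0]
  }
  ks <- lengths(vs)
  if (is.null(max_lag)) max_lag <- max(ks) - 2L
  max_lag <- min(max_lag, max(ks) - 1L)
  lags <- 0:max_lag
  # per-trace mean-subtracted autocovariance, 1/(K-r) per-pair normalisation
  nmat <- matrix(NA_real_, length(vs), length(lags))
  for (a in seq_along(vs)) {
    v <- vs[[a]]
    K <- length(v)
    lm <- min(max_lag, K - 1L)
    ac <- stats::acf(v, lag.max = lm, plot = FALSE, demean = TRUE,
                     type = "covariance")$acf[, 1, 1]
    nmat[a, seq_len(lm + 1)] <- ac * K / (K - (0:lm))
  }
  cmat <- if (variance == "per_trace") nmat / vars
          else nmat / mean(vars)
  n_at <- colSums(!is.na(cmat))
  val0 <- colMeans(cmat, na.rm = TRUE)
  se0 <- apply(cmat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_at, 1))
  c1 <- val0[2]
  pair <- vapply(lags, function(r) sum(pmax(ks - r, 0)), numeric(1))
  out <- data.frame(lag = lags, lag_s = lags * dt, value = val0 / c1,
                    value_raw = val0, pair_count = pair, se = se0 / abs(c1),
                    n_traces = n_at)
  structure(out, class = c("correlation_curve", "data.frame"),
            normalization = "lag1", variance = variance, dt_s = dt)
}

#' Empirical cross-correlation between two aligned trace sets
#'
#' Connected cross-correlation of paired traces (same nuclei, two colour
#' channels), mean-subtracted per trace and normalised per trace by the
#' geometric mean of the two channel variances, then averaged over pairs.
#' Positive lags mean channel `b` lags channel `a`.
#'
#' @param traces_a,traces_b Aligned [trace_set()]s with equal trace counts
#'   and grids.
#' @param max_lag Largest |lag| in samples.
#' @return A `correlation_curve` data frame over lags `-max_lag .. max_lag`
#'   (normalisation tag `"variance"`).
#' @export
empirical_cross_correlation <- function(traces_a, traces_b, max_lag = NULL) {
  stopifnot(n_traces(traces_a) == n_traces(traces_b))
  dt <- common_dt(traces_a)
  va <- steady_values(traces_a); vb <- steady_values(traces_b)
  K <- unique(c(lengths(va), lengths(vb)))
  if (length(K) != 1) stop("paired traces must share one grid")
  if (is.null(max_lag)) max_lag <- K - 2L
  lags <- (-max_lag):max_lag
  cmat <- matrix(NA_real_, length(va), length(lags))
  for (p in seq_along(va)) {
    x <- va[[p]] - mean(va[[p]]); y <- vb[[p]] - mean(vb[[p]])
    sxy <- sqrt(mean(x^2) * mean(y^2))
    if (sxy == 0) next
    cc <- vapply(lags, function(r) {
      i <- seq_len(K - abs(r))
      if (r >= 0) mean(x[i] * y[i + r]) else mean(x[i + abs(r)] * y[i])
    }, numeric(1))
    cmat[p, ] <- cc / sxy
  }
  val <- colMeans(cmat, na.rm = TRUE)
  out <- data.frame(lag = lags, lag_s = lags * dt, value = val,
                    value_raw = val,
                    pair_count = n_traces(traces_a) * (K - abs(lags)),
                    se = apply(cmat, 2, stats::sd, na.rm = TRUE) /
                      sqrt(colSums(!is.na(cmat))))
  structure(out, class = c("correlation_curve", "data.frame"),
            normalization = "variance", dt_s = dt)
}

#' Infinite-trace autocovariance of the fluorescence signal
#'
#' Returns a function `f(tau_s)` evaluating the connected autocovariance
#' (loop units squared)
#' `C(tau) = P_on * sum_d w_d (A(|tau - d * step|) - P_on)`,
#' where `w_d = sum_i L_i L_{i+d}` collects the loop-function double sum by
#' site offset `d` and `A` is the model's ON-ON propagator. Because the
#' propagator is continuous in time the covariance can be evaluated exactly
#' at any real lag, whether or not it aligns with the polymerase step grid.
#'
#' @param model A `promoter_model`.
#' @param loop_fn Loop function of the observed channel.
#' @param loop_fn_b Optional second channel for a cross-covariance
#'   `<F_a(t) F_b(t+tau)>_c` (asymmetric in the lag sign).
#' @param step_time_s Seconds per polymerase step.
#' @return Function mapping lag(s) in seconds to covariance values.
#' @export
autocovariance_function <- function(model, loop_fn, loop_fn_b = NULL,
                                    step_time_s = 6) {
  La <- as.numeric(loop_fn)
  Lb <- if (is.null(loop_fn_b)) La else as.numeric(loop_fn_b)
  stopifnot(length(La) == length(Lb))
  r <- length(La)
  pon <- stationary_on_probability(model)
  dvals <- -(r - 1):(r - 1)
  w <- vapply(dvals, function(d) {
    i <- seq_len(r)
    ok <- i + d >= 1 & i + d <= r
    sum(La[i[ok]] * Lb[i[ok] + d])
  }, numeric(1))
  dsec <- dvals * step_time_s
  function(tau_s) {
    tt <- abs(outer(tau_s, dsec, "-"))
    ut <- sort(unique(as.numeric(tt)))
    au <- propagator_seconds(model, ut)
    A <- matrix(au[match(as.numeric(tt), ut)], nrow = length(tau_s))
    as.numeric(A %*% w) * pon - pon^2 * sum(w)
  }
}

#' Theoretical (infinite-trace) autocorrelation curve
#'
#' The model autocovariance normalised by its variance, `C(tau)/C(0)`,
#' evaluated at the requested lags. This is the long-trace limit; compare
#' against data via [finite_trace_correction()].
#'
#' @param model A `promoter_model`.
#' @param loop_fn Loop function.
#' @param lags_s Lags in seconds.
#' @param step_time_s Seconds per polymerase step.
#' @return A `correlation_curve` data frame (normalisation tag
#'   `"variance"`).
#' @export
theoretical_autocorrelation <- function(model, loop_fn, lags_s,
                                        step_time_s = 6) {
  f <- autocovariance_function(model, loop_fn, step_time_s = step_time_s)
  v0 <- f(0)
  val <- f(lags_s) / v0
  structure(data.frame(lag = lags_s / step_time_s, lag_s = lags_s,
                       value = val, value_raw = val,
                       pair_count = NA_real_, se = NA_real_),
            class = c("correlation_curve", "data.frame"),
            normalization = "variance", dt_s = NA_real_,
            variance = v0)
}

#' Theoretical cross-correlation between two probe placements
#'
#' Cross-covariance of the two channels driven by one promoter, normalised
#' by the geometric mean of the channel variances. Asymmetric in the lag
#' sign unless the loop functions coincide, in which case it equals
#' [theoretical_autocorrelation()]. Positive lags mean channel `b` lags
#' channel `a`.
#'
#' @inheritParams theoretical_autocorrelation
#' @param loop_fn_a,loop_fn_b Loop functions of the two channels (same gene
#'   grid).
#' @return A `correlation_curve` data frame.
#' @export
theoretical_cross_correlation <- function(model, loop_fn_a, loop_fn_b,
                                          lags_s, step_time_s = 6) {
  fab <- autocovariance_function(model, loop_fn_a, loop_fn_b, step_time_s)
  fa <- autocovariance_function(model, loop_fn_a, step_time_s = step_time_s)
  fb <- autocovariance_function(model, loop_fn_b, step_time_s = step_time_s)
  norm <- sqrt(fa(0) * fb(0))
  val <- fab(lags_s) / norm
  structure(data.frame(lag = lags_s / step_time_s, lag_s = lags_s,
                       value = val, value_raw = val,
                       pair_count = NA_real_, se = NA_real_),
            class = c("correlation_curve", "data.frame"),
            normalization = "variance", dt_s = NA_real_)
}

#' Finite-trace correction of a theoretical autocorrelation
#'
#' The empirical connected autocorrelation of a short trace is biased: the
#' empirical mean is correlated with every sample, which forces the area
#' under the curve to zero and digs a spurious negative valley at
#' intermediate lags. This function computes the *exact expectation* of the
#' mean-subtracted empirical autocovariance estimator for a trace of `K`
#' samples,
#' \deqn{E[(v_i - m)(v_j - m)] = \Sigma_{ij} - (R_i + R_j)/K + S/K^2,}
#' with `m` the empirical mean, `Sigma` the true covariance matrix of the
#' sampled signal, `R_i` its row sums and `S` its grand sum, averaged over
#' the `K - r` pairs at each lag and normalised at lag 1 (matching
#' [connected_autocorrelation()]). As `K` grows the corrected curve
#' converges to the normalised infinite-trace curve.
#'
#' When `step_time_s` is supplied, sample `k` is mapped to its nearest
#' polymerase step (the same lookup used when sampling simulated
#' step-resolved signals), so sampling grids incommensurate with the step
#' time are handled exactly; otherwise sample times are `k * dt_s`.
#'
#' @param autocov Autocovariance function of lag in seconds, e.g. from
#'   [autocovariance_function()], or any user-supplied function (for
#'   processes such as the Ornstein-Uhlenbeck oracle).
#' @param K Trace length in samples (at least 3).
#' @param dt_s Sampling interval (s).
#' @param step_time_s Polymerase step time (s) for step-held signals, or
#'   `NULL` for continuously sampled processes.
#' @return A `correlation_curve` data frame over lags `0 .. K-1`
#'   (normalisation tag `"lag1"`; `value_raw` holds the unnormalised
#'   expected autocovariance).
#' @export
finite_trace_correction <- function(autocov, K, dt_s, step_time_s = NULL) {
  if (K < 3) stop("trace too short: need K >= 3 samples")
  stopifnot(is.function(autocov))
  t_k <- if (is.null(step_time_s)) (0:(K - 1)) * dt_s
         else round((0:(K - 1)) * dt_s / step_time_s) * step_time_s
  dmat <- abs(outer(t_k, t_k, "-"))
  ut <- sort(unique(as.numeric(dmat)))
  cv <- autocov(ut)
  Sig <- matrix(cv[match(as.numeric(dmat), ut)], K, K)
  R <- rowSums(Sig)
  S2 <- sum(R)
  en <- vapply(0:(K - 1), function(r) {
    i <- seq_len(K - r)
    mean(Sig[cbind(i, i + r)]) - mean(R[i] + R[i + r]) / K + S2 / K^2
  }, numeric(1))
  c1 <- en[2]
  structure(data.frame(lag = 0:(K - 1), lag_s = (0:(K - 1)) * dt_s,
                       value = en / c1, value_raw = en,
                       pair_count = K - (0:(K - 1)), se = NA_real_),
            class = c("correlation_curve", "data.frame"),
            normalization = "lag1", dt_s = dt_s)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation_curve: %d lags, dt %s s, normalised at %s\n",
              nrow(x), format(attr(x, "dt_s")), attr(x, "normalization")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Write / read a correlation curve as delimited text
#' @param curve A `correlation_curve`.
#' @param path File path.
#' @return `read_correlation` returns a `correlation_curve`.
#' @export
write_correlation <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("correlation_curve", "data.frame"),
            normalization = "unknown",
            dt_s = if (nrow(df) > 1) df$lag_s[2] - df$lag_s[1] else NA_real_)
}
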