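# Evaluate expr with a local, restorable RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One seed per nucleus so trace sets are reproducible regardless of how the
# per-trace work is ordered.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Simulate a promoter state trace
#'
#' Exact continuous-time simulation of the switching process (exponential ON
#' dwells; model-specific OFF dwells), binarised onto the polymerase-step
#' grid by the state at each step start. The chain starts in its stationary
#' law (for the Gamma model, via a burn-in of 20 mean switching periods,
#' since the stationary residual OFF time is not exponential). The
#' Poisson-like promoter draws independent per-step initiation events with
#' probability `P_on`.
#'
#' @param model A `promoter_model`.
#' @param duration_s Trace duration in seconds (at least one step).
#' @param step_time_s Seconds per polymerase step.
#' @param seed Optional integer seed (same seed, same trace).
#' @param init `"stationary"` (default) or `"off"` to start in the first
#'   OFF state (e.g. right after mitosis).
#' @return Integer vector of 0/1 states, one per step, with attribute
#'   `step_time_s`.
#' @export
simulate_promoter_trace <- function(model, duration_s, step_time_s = 6,
                                    seed = NULL, init = c("stationary", "off")) {
  init <- match.arg(init)
  stopifnot(duration_s >= step_time_s)
  n_steps <- ceiling(duration_s / step_time_s)
  with_seed(seed, {
    x <- if (inherits(model, "poisson_promoter")) {
      as.integer(stats::runif(n_steps) < model$p_on)
    } else {
      sim_switching_states(model, n_steps, step_time_s, init)
    }
    attr(x, "step_time_s") <- step_time_s
    x
  })
}

# Continuous-time dwell sequence -> state at step starts.
sim_switching_states <- function(model, n_steps, step_time_s, init) {
  total <- n_steps * step_time_s
  pon <- stationary_on_probability(model)
  burn <- 0
  if (init == "stationary") {
    if (inherits(model, "gamma_promoter")) {
      # stationary residual OFF time is not exponential: burn in instead
      burn <- 20 * (1 / model$k_off + model$alpha / model$beta)
      on <- TRUE
    } else {
      on <- stats::runif(1) < pon
    }
  } else on <- FALSE
  # for a cycle chain starting OFF in stationarity, pick the OFF stage
  # with probability proportional to its mean dwell
  off_stage <- 1L
  if (init == "stationary" && inherits(model, "cycle") && !on) {
    w <- (1 / model$off_rates) / sum(1 / model$off_rates)
    off_stage <- sample.int(model$K, 1, prob = w)
  }
  t_end <- burn + total
  cap <- 64L
  times <- numeric(cap); states <- integer(cap)
  t <- 0; k <- 0L
  while (t < t_end) {
    k <- k + 1L
    if (k > cap) {  # grow storage geometrically
      cap <- 2L * cap
      length(times) <- cap; length(states) <- cap
    }
    times[k] <- t
    states[k] <- as.integer(on)
    if (on) {
      t <- t + stats::rexp(1, model$k_off)
    } else {
      t <- t + off_dwell(model, off_stage)
      off_stage <- 1L
    }
    on <- !on
  }
  grid <- burn + (seq_len(n_steps) - 1) * step_time_s
  idx <- findInterval(grid, times[seq_len(k)])
  states[pmax(idx, 1L)]
}

# One full OFF dwell (from OFF stage `stage` onward for the cycle model).
off_dwell <- function(model, stage = 1L) {
  if (inherits(model, "two_state")) {
    stats::rexp(1, model$k_on)
  } else if (inherits(model, "cycle")) {
    sum(stats::rexp(model$K - stage + 1L,
                    model$off_rates[stage:model$K]))
  } else if (inherits(model, "gamma_promoter")) {
    stats::rgamma(1, shape = model$alpha, rate = model$beta)
  } else stop("unsupported model for dwell simulation")
}

#' Simulate a set of fluorescence traces
#'
#' For each nucleus a promoter state history is simulated, mapped to
#' fluorescence through the construct's loop function, and sampled on the
#' observation grid by nearest-step lookup. The gene is pre-loaded (the
#' loading transient of `r` steps is simulated and discarded) so recorded
#' traces are stationary from the first sample.
#'
#' @param model A `promoter_model`.
#' @param construct A [gene_construct()].
#' @param n_nuclei Number of traces M.
#' @param duration_s Recorded duration T (s).
#' @param dt_s Sampling interval (s); need not equal the polymerase step
#'   time (sampling faster than the step time duplicates steps).
#' @param seed Optional master seed; per-nucleus substreams are derived
#'   from it.
#' @param noise_sd SD of optional additive white observation noise (loop
#'   units, before the intensity scale is applied).
#' @param intensity_per_loop Intensity units per fluorescing loop (the
#'   calibration factor I0 a real experiment does not know).
#' @return A [trace_set()] in intensity units, all samples marked steady
#'   state.
#' @export
simulate_trace_set <- function(model, construct, n_nuclei, duration_s,
                               dt_s, seed = NULL, noise_sd = 0,
                               intensity_per_loop = 1) {
  L <- build_loop_function(construct)
  sim_set_with_loops(model, list(L), construct$step_time_s, n_nuclei,
                     duration_s, dt_s, seed, noise_sd,
                     intensity_per_loop)[[1]]
}

#' Simulate a two-colour trace set
#'
#' Both channels are driven by the identical promoter realisation per
#' nucleus; only the loop functions (probe placements) differ.
#'
#' @inheritParams simulate_trace_set
#' @param construct_a,construct_b Constructs of the two channels; must share
#'   `step_time_s`.
#' @return List of two aligned [trace_set()]s, `a` and `b`.
#' @export
simulate_two_color <- function(model, construct_a, construct_b, n_nuclei,
                               duration_s, dt_s, seed = NULL, noise_sd = 0,
                               intensity_per_loop = 1) {
  stopifnot(construct_a$step_time_s == construct_b$step_time_s)
  Ls <- list(build_loop_function(construct_a),
             build_loop_function(construct_b))
  out <- sim_set_with_loops(model, Ls, construct_a$step_time_s, n_nuclei,
                            duration_s, dt_s, seed, noise_sd,
                            intensity_per_loop)
  names(out) <- c("a", "b")
  out
}

sim_set_with_loops <- function(model, loop_fns, step_time_s, n_nuclei,
                               duration_s, dt_s, seed, noise_sd,
                               intensity_per_loop) {
  stopifnot(n_nuclei >= 1, duration_s > 0, dt_s > 0)
  r <- max(lengths(loop_fns))
  t_obs <- seq(0, duration_s, by = dt_s)
  step_idx <- round(t_obs / step_time_s)  # nearest-step lookup
  n_steps <- max(step_idx) + 1L
  seeds <- spawn_seeds(seed, n_nuclei)
  chans <- lapply(loop_fns, function(.) vector("list", n_nuclei))
  for (m in seq_len(n_nuclei)) {
    x <- simulate_promoter_trace(model, (n_steps + r) * step_time_s,
                                 step_time_s, seed = seeds[m])
    for (ch in seq_along(loop_fns)) {
      f <- fluorescence_from_states(x, loop_fns[[ch]])
      rc <- length(loop_fns[[ch]])
      fss <- f[(rc + 1):length(f)]          # drop loading transient
      v <- fss[step_idx + 1L]
      if (noise_sd > 0)
        v <- v + with_seed(seeds[m] + 1L, stats::rnorm(length(v), 0, noise_sd))
      chans[[ch]][[m]] <- v * intensity_per_loop
    }
  }
  lapply(chans, function(intens)
    trace_set(intens, rep(list(t_obs), n_nuclei),
              meta = data.frame(nucleus_id = seq_len(n_nuclei))))
}
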