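#' Generate an embryo-like synthetic dataset
#'
#' Emulates the study design: several embryos imaged at different sampling
#' intervals through cell cycles 11-13, each nucleus carrying a two-state
#' promoter whose ON rate decays along the anterior-posterior axis with the
#' Bicoid length scale while the OFF rate rises slowly, so that the ON
#' probability falls from ~0.5 in the anterior to ~0.1 at the boundary.
#' Nuclei double between cycles with lineage links; each interphase starts
#' with the promoter OFF and an empty gene (activation ramp), and
#' transcription shuts down before mitosis (decay), so the plateau in
#' between is the steady-state window. Mitosis itself is a gap between
#' cycles, not modelled.
#'
#' @param n_embryos Number of embryos.
#' @param dt_s Sampling interval per embryo (s); recycled to `n_embryos`.
#' @param cycles Cell-cycle labels.
#' @param interphase_s Interphase duration per cycle (s).
#' @param n_nuclei_final Nuclei at the last cycle (halved per earlier
#'   cycle); positions are spread uniformly over `ap_range`.
#' @param ap_range Range of nucleus positions (fraction of egg length).
#' @param k_on_anterior,k_off_anterior Anterior switching rates (1/s).
#' @param embryo_length_um,lambda_kon_um Embryo length and ON-rate decay
#'   length (the Bicoid gradient scale, 100 um).
#' @param lambda_koff_um OFF-rate growth length scale (um).
#' @param anterior_ref Position (fraction of egg length) where the
#'   anterior rates apply; the ON rate is flat anterior to it.
#' @param shutdown_s Seconds of forced promoter silence before mitosis.
#' @param construct Reporter [gene_construct()].
#' @param intensity_per_loop Intensity units per loop (the I0 the analysis
#'   must re-estimate).
#' @param noise_sd Additive white observation noise (loop units).
#' @param seed Master seed; generation is fully reproducible.
#' @return A [trace_set()] with position, cycle, lineage metadata; raw
#'   (unmarked) steady-state masks.
#' @export
generate_embryo_dataset <- function(n_embryos = 4,
                                    dt_s = c(13.1, 10.2, 5.1, 4.3),
                                    cycles = 11:13,
                                    interphase_s = c(360, 540, 780),
                                    n_nuclei_final = 300,
                                    ap_range = c(0, 0.6),
                                    k_on_anterior = 0.015,
                                    k_off_anterior = 0.015,
                                    embryo_length_um = 500,
                                    lambda_kon_um = 100,
                                    lambda_koff_um = 275,
                                    anterior_ref = 0.175,
                                    shutdown_s = 120,
                                    construct = construct_3prime(),
                                    intensity_per_loop = 20,
                                    noise_sd = 0,
                                    seed = NULL) {
  stopifnot(length(cycles) == length(interphase_s), n_nuclei_final >= 4,
            lambda_kon_um > 0, lambda_koff_um > 0)
  dt_s <- rep_len(dt_s, n_embryos)
  L <- build_loop_function(construct)
  step <- construct$step_time_s
  eseeds <- spawn_seeds(seed, n_embryos * 2)
  n_by_cycle <- rev(round(n_nuclei_final / 2^(seq_along(cycles) - 1)))
  intensity <- list(); time_s <- list(); meta <- NULL
  for (e in seq_len(n_embryos)) {
    # founder positions, then daughters jitter around their mother
    pos <- list()
    pos[[1]] <- with_seed(eseeds[2 * e - 1],
                          sort(stats::runif(n_by_cycle[1], ap_range[1],
                                            ap_range[2])))
    for (ci in seq_along(cycles)[-1]) {
      mother <- rep(seq_len(n_by_cycle[ci - 1]), each = 2)
      pos[[ci]] <- with_seed(eseeds[2 * e - 1] + ci,
                             pmin(pmax(pos[[ci - 1]][mother] +
                                         stats::rnorm(n_by_cycle[ci], 0, 0.008),
                                       ap_range[1]), ap_range[2]))
    }
    for (ci in seq_along(cycles)) {
      x <- pos[[ci]]
      k_on <- k_on_anterior *
        pmin(1, exp(-(x - anterior_ref) * embryo_length_um / lambda_kon_um))
      k_off <- k_off_anterior *
        pmax(1, exp((x - anterior_ref) * embryo_length_um / lambda_koff_um))
      nseeds <- spawn_seeds(eseeds[2 * e] + ci, n_by_cycle[ci])
      t_obs <- seq(0, interphase_s[ci], by = dt_s[e])
      step_idx <- round(t_obs / step)
      n_steps <- max(step_idx) + 1L
      active_steps <- max(1L, n_steps - ceiling(shutdown_s / step))
      for (m in seq_len(n_by_cycle[ci])) {
        mdl <- two_state_model(k_on[m], k_off[m])
        x_states <- simulate_promoter_trace(mdl, n_steps * step, step,
                                            seed = nseeds[m], init = "off")
        x_states[(active_steps + 1):n_steps] <- 0L  # pre-mitotic shutdown
        f <- fluorescence_from_states(x_states, L)  # ramp kept: gene starts empty
        v <- f[step_idx + 1L]
        if (noise_sd > 0)
          v <- v + with_seed(nseeds[m] + 1L,
                             stats::rnorm(length(v), 0, noise_sd))
        intensity[[length(intensity) + 1L]] <- v * intensity_per_loop
        time_s[[length(time_s) + 1L]] <- t_obs
        meta <- rbind(meta, data.frame(
          embryo_id = e, cycle = cycles[ci], nucleus_id = m,
          ap_position = x[m],
          mother_id = if (ci == 1) NA_integer_ else ((m + 1L) %/% 2L)))
      }
    }
  }
  trace_set(intensity, time_s, meta)
}

#' Local switching rates of the synthetic embryo at a position
#'
#' The deterministic ON/OFF rate profile used by
#' [generate_embryo_dataset()]; handy for comparing inferred against true
#' kinetics.
#'
#' @inheritParams generate_embryo_dataset
#' @param ap_position Position(s), fraction of egg length.
#' @return Data frame with `ap_position`, `k_on`, `k_off`, `p_on`.
#' @export
embryo_kinetics_profile <- function(ap_position, k_on_anterior = 0.015,
                                    k_off_anterior = 0.015,
                                    embryo_length_um = 500,
                                    lambda_kon_um = 100,
                                    lambda_koff_um = 275,
                                    anterior_ref = 0.175) {
  k_on <- k_on_anterior *
    pmin(1, exp(-(ap_position - anterior_ref) * embryo_length_um /
                  lambda_kon_um))
  k_off <- k_off_anterior *
    pmax(1, exp((ap_position - anterior_ref) * embryo_length_um /
                  lambda_koff_um))
  data.frame(ap_position = ap_position, k_on = k_on, k_off = k_off,
             p_on = k_on / (k_on + k_off))
}

#' Generate Ornstein-Uhlenbeck traces
#'
#' Euler-Maruyama integration of `dx = -lambda x dt + gamma dW` from a
#' stationary start, subsampled onto the observation grid. The stationary
#' variance is `gamma^2 / (2 lambda)` and the autocorrelation time
#' `1/lambda`; short traces of this process reproduce the finite-trace
#' autocorrelation artifacts of the promoter signal in a setting with an
#' exact closed form, making it the validation oracle for
#' [finite_trace_correction()].
#'
#' @param lambda Relaxation rate (1/s).
#' @param gamma_noise Noise amplitude (units / sqrt(s)).
#' @param duration_s Trace duration (s).
#' @param n Number of traces.
#' @param dt_s Observation sampling interval (s).
#' @param dt_sim Internal integration step (s); a warning is raised if
#'   `lambda * dt_sim > 0.1` (integration too coarse to trust).
#' @param seed Optional seed.
#' @return A [trace_set()] (values may be negative; this is a raw process,
#'   not an intensity).
#' @export
generate_ou_traces <- function(lambda, gamma_noise, duration_s, n,
                               dt_s = 0.1, dt_sim = NULL, seed = NULL) {
  stopifnot(lambda > 0, gamma_noise > 0, duration_s > 0, n >= 1)
  if (is.null(dt_sim)) dt_sim <- min(dt_s, 0.02 / lambda)
  if (lambda * dt_sim > 0.1)
    warning("lambda * dt_sim > 0.1: Euler-Maruyama step too coarse")
  sub <- max(1L, round(dt_s / dt_sim))
  dt_sim <- dt_s / sub
  n_obs <- floor(duration_s / dt_s) + 1L
  n_steps <- (n_obs - 1L) * sub
  with_seed(seed, {
    x <- stats::rnorm(n, 0, gamma_noise / sqrt(2 * lambda))
    out <- matrix(0, n, n_obs)
    out[, 1] <- x
    j <- 1L
    for (s in seq_len(n_steps)) {
      x <- x - lambda * x * dt_sim +
        gamma_noise * sqrt(dt_sim) * stats::rnorm(n)
      if (s %% sub == 0L) { j <- j + 1L; out[, j] <- x }
    }
    tt <- (seq_len(n_obs) - 1L) * dt_s
    trace_set(lapply(seq_len(n), function(i) out[i, ]), rep(list(tt), n),
              meta = data.frame(nucleus_id = seq_len(n)))
  })
}
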