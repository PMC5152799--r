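#' Readout precision of a two-state promoter
#'
#' The relative error of the mRNA produced during a steady-state window of
#' duration `T`: the gene makes roughly `T / tau_i` independent measurements
#' of its regulatory environment, where `tau_i = 1/(k_on_eff + k_off)` is
#' the promoter relaxation time, so
#' \deqn{\delta mRNA/\langle mRNA\rangle =
#'   \sqrt{2 \tau_i (1 - P_{on}) / (T P_{on})}.}
#' The factor 2 corrects the naive independent-measurement count; the
#' expression is the large-`T` limit (`T >> tau_i`) and matches the variance
#' of the time-averaged ON indicator of the telegraph process in that limit.
#'
#' @param k_on,k_off Switching rates (1/s); for a cycle model pass
#'   `k_on = effective_on_rate(model)`.
#' @param T_s Measurement window (s).
#' @return A `precision_estimate` data frame row (dimensionless relative
#'   error).
#' @export
relative_error_two_state <- function(k_on, k_off, T_s) {
  stopifnot(k_on > 0, k_off > 0, T_s > 0)
  p <- k_on / (k_on + k_off)
  tau_i <- 1 / (k_on + k_off)
  precision_estimate(sqrt(2 * tau_i * (1 - p) / (T_s * p)),
                     kind = "theory-two-state", T_s = T_s, tau_i = tau_i)
}

#' Readout precision of a Poisson-like promoter
#'
#' For the static promoter firing at Poisson rate `r` with deterministic
#' blocking time `tau_block`, the occupied fraction is
#' `P_on = tau_block / (tau_block + 1/r)` and the relative error of the
#' produced mRNA over a window `T` is
#' \deqn{\delta mRNA/\langle mRNA\rangle = \sqrt{\tau_{block}(1-P_{on})/T}.}
#'
#' @param p_on Occupied fraction `P_on` of the initiation site; supply
#'   either this or `firing_rate`.
#' @param firing_rate Poisson rate `r` (1/s).
#' @param tau_block Blocking time (s).
#' @param T_s Measurement window (s).
#' @return A `precision_estimate` data frame row.
#' @export
relative_error_poisson <- function(T_s, tau_block = 6, p_on = NULL,
                                   firing_rate = NULL) {
  stopifnot(T_s > 0, tau_block > 0)
  if (is.null(p_on)) {
    stopifnot(!is.null(firing_rate))
    p_on <- tau_block / (tau_block + 1 / firing_rate)
  }
  stopifnot(p_on >= 0, p_on <= 1)
  precision_estimate(sqrt(tau_block * (1 - p_on) / T_s),
                     kind = "theory-poisson", T_s = T_s,
                     tau_i = tau_block / max(p_on, .Machine$double.eps))
}

precision_estimate <- function(value, kind, T_s, tau_i = NA_real_,
                               label = NA_character_, n = NA_integer_) {
  structure(data.frame(rel_error = value, kind = kind, T_s = T_s,
                       tau_i = tau_i, label = label, n = n),
            class = c("precision_estimate", "data.frame"))
}

#' Monte-Carlo readout precision for any promoter model
#'
#' Simulates `n_realizations` promoter state histories of duration `T`,
#' time-averages the ON indicator over each window, and reports the SD over
#' realisations divided by the mean. This is the finite-`T` ground truth the
#' closed-form expressions approximate; for the two-state model it converges
#' to the large-`T` formula once `T >~ 10 tau_i`.
#'
#' @param model A `promoter_model`.
#' @param T_s Window duration (s).
#' @param n_realizations Number of independent windows (>= 100 recommended).
#' @param step_time_s Discretisation of the window (s).
#' @param seed Optional seed.
#' @return A `precision_estimate` data frame row.
#' @export
relative_error_monte_carlo <- function(model, T_s, n_realizations = 1000,
                                       step_time_s = 6, seed = NULL) {
  stopifnot(T_s > 0)
  if (n_realizations < 100)
    warning("fewer than 100 realizations; the error estimate will be noisy")
  seeds <- spawn_seeds(seed, n_realizations)
  occ <- vapply(seq_len(n_realizations), function(i) {
    mean(simulate_promoter_trace(model, T_s, step_time_s, seed = seeds[i]))
  }, numeric(1))
  precision_estimate(stats::sd(occ) / mean(occ), kind = "monte-carlo",
                     T_s = T_s, n = n_realizations)
}

#' Empirical readout precision per spatial bin
#'
#' For each anterior-posterior bin, the SD over nuclei of the time-averaged
#' activity (or total produced signal) divided by its mean: the
#' nucleus-to-nucleus relative error of the transcriptional readout at that
#' position.
#'
#' @param traces Calibrated [trace_set()] with `ap_position` metadata.
#' @param bin_width Bin width as a fraction of egg length (default 0.1).
#' @param statistic `"mean"` (time-averaged steady-state activity per
#'   nucleus), `"total"` (integrated intensity) or `"binary"` (1 if the
#'   nucleus was ever active, the fixed-sample convention).
#' @param min_nuclei Bins with fewer nuclei are dropped with a warning.
#' @return A `precision_estimate` data frame, one row per bin, with
#'   `label` the bin centre (fraction of egg length) and `n` the nucleus
#'   count.
#' @export
empirical_relative_error <- function(traces, bin_width = 0.1,
                                     statistic = c("mean", "total", "binary"),
                                     min_nuclei = 3) {
  statistic <- match.arg(statistic)
  pos <- traces$meta$ap_position
  if (all(is.na(pos))) stop("traces carry no ap_position metadata")
  vs <- steady_values(traces)
  per_nuc <- vapply(seq_along(vs), function(i) {
    v <- vs[[i]]
    dt <- traces$meta$dt_s[i]
    switch(statistic,
           mean = mean(v),
           total = sum(v) * dt,
           binary = as.numeric(any(v > 0)))
  }, numeric(1))
  bins <- floor(pos / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bins[!is.na(bins)])), function(b) {
    x <- per_nuc[!is.na(bins) & bins == b]
    if (length(x) < min_nuclei || mean(x) == 0) return(NULL)
    precision_estimate(stats::sd(x) / mean(x),
                       kind = paste0("empirical-", statistic),
                       T_s = NA_real_, label = sprintf("%.3f", (b + 0.5) *
                                                        bin_width),
                       n = length(x))
  }))
  if (is.null(out)) {
    warning("no bin had at least ", min_nuclei, " nuclei")
    return(precision_estimate(numeric(0), kind = character(0),
                              T_s = numeric(0), tau_i = numeric(0),
                              label = character(0), n = integer(0)))
  }
  dropped <- length(unique(bins[!is.na(bins)])) - nrow(out)
  if (dropped > 0)
    warning(dropped, " bin(s) dropped (fewer than ", min_nuclei,
            " nuclei or zero mean)")
  out
}

#' Lineage-integrated readout precision per spatial bin
#'
#' Integrates each nucleus' produced signal over cell cycles, inheriting
#' half of the mother's total and a quarter of the grandmother's (mRNA is
#' split between daughters at division), then computes the per-bin relative
#' error of the integrated totals at the final cycle.
#'
#' @param traces Calibrated [trace_set()] spanning several cell cycles with
#'   `mother_id` links.
#' @param final_cycle Cycle whose nuclei are evaluated (default: the
#'   largest cycle label present).
#' @param bin_width Bin width in fraction of egg length.
#' @param min_nuclei Minimum nuclei per bin.
#' @return A `precision_estimate` data frame (one row per bin) with
#'   attribute `skipped`, the number of nuclei dropped for broken lineage.
#' @export
lineage_integrated_error <- function(traces, final_cycle = NULL,
                                     bin_width = 0.1, min_nuclei = 3) {
  meta <- traces$meta
  if (is.null(final_cycle)) final_cycle <- max(meta$cycle, na.rm = TRUE)
  vs <- steady_values(traces)
  totals <- vapply(seq_along(vs), function(i) sum(vs[[i]]) * meta$dt_s[i],
                   numeric(1))
  key <- paste(meta$embryo_id, meta$cycle, meta$nucleus_id)
  idx <- which(meta$cycle == final_cycle)
  skipped <- 0L
  integ <- pos <- numeric(0)
  for (i in idx) {
    tot <- totals[i]
    ok <- TRUE
    mom <- match(paste(meta$embryo_id[i], final_cycle - 1, meta$mother_id[i]),
                 key)
    if (!is.na(mom)) {
      tot <- tot + totals[mom] / 2
      gran <- match(paste(meta$embryo_id[i], final_cycle - 2,
                          meta$mother_id[mom]), key)
      if (!is.na(gran)) tot <- tot + totals[gran] / 4
      else if (any(meta$cycle == final_cycle - 2, na.rm = TRUE)) ok <- FALSE
    } else if (any(meta$cycle == final_cycle - 1, na.rm = TRUE)) {
      ok <- FALSE
    }
    if (!ok) { skipped <- skipped + 1L; next }
    integ <- c(integ, tot)
    pos <- c(pos, meta$ap_position[i])
  }
  if (skipped > 0)
    warning(skipped, " nucleus/nuclei skipped for broken lineage links")
  bins <- floor(pos / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bins[!is.na(bins)])), function(b) {
    x <- integ[!is.na(bins) & bins == b]
    if (length(x) < min_nuclei || mean(x) == 0) return(NULL)
    precision_estimate(stats::sd(x) / mean(x), kind = "empirical-lineage",
                       T_s = NA_real_,
                       label = sprintf("%.3f", (b + 0.5) * bin_width),
                       n = length(x))
  }))
  structure(out, skipped = skipped)
}

#' How much longer must the gene integrate to reach a target precision?
#'
#' Under the independent-measurement scaling the relative error falls as
#' `T^(-1/2)`, so reaching `target_error` from `current_error` requires
#' integrating `(current/target)^2` times longer. A factor <= 1 means no
#' extra integration is needed.
#'
#' @param current_error,target_error Relative errors (> 0).
#' @return Multiplicative factor on the integration time.
#' @export
integration_time_factor <- function(current_error, target_error) {
  stopifnot(current_error > 0, target_error > 0)
  (current_error / target_error)^2
}
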