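#' Promoter switching models
#'
#' Four schemes for the stochastic activity of a promoter:
#' \describe{
#'   \item{two-state (telegraph)}{exponential ON and OFF dwell times with
#'     rates `k_off` and `k_on`.}
#'   \item{cycle}{an ON state plus an irreversible chain of K OFF states,
#'     left at rates `k_1 .. k_K`; OFF dwell times are hypoexponential.}
#'   \item{Gamma}{an effective two-state model whose OFF waiting times follow
#'     a Gamma(shape `alpha`, rate `beta`) distribution. With integer `alpha`
#'     and all cycle rates equal to `beta` this is exactly the cycle model.}
#'   \item{Poisson-like}{a static promoter: initiation events fire at Poisson
#'     rate `r`, each blocking the site for the deterministic `tau_block`.
#'     Successive polymerase steps are uncorrelated.}
#' }
#' All rates are in 1/s. Per-step quantities are obtained by multiplying by
#' the polymerase step time at the model/signal boundary; the printed
#' exponential propagators are valid when `rate * step_time < 1`.
#'
#' @param k_on,k_off Switching rates (1/s).
#' @return An object of class `promoter_model`.
#' @name promoter_models
NULL

#' @rdname promoter_models
#' @export
two_state_model <- function(k_on, k_off) {
  stopifnot(k_on > 0, k_off > 0)
  structure(list(k_on = k_on, k_off = k_off),
            class = c("two_state", "promoter_model"))
}

#' @rdname promoter_models
#' @param off_rates Rates `k_1 .. k_K` (1/s) for leaving the K sequential OFF
#'   states. Stored sorted increasing: the ordering of the OFF rates is not
#'   identifiable from a single-colour experiment.
#' @export
cycle_model <- function(k_off, off_rates) {
  stopifnot(k_off > 0, length(off_rates) >= 1, all(off_rates > 0))
  off_rates <- sort(off_rates)
  m <- structure(list(k_off = k_off, off_rates = off_rates,
                      K = length(off_rates)),
                 class = c("cycle", "promoter_model"))
  m$transition_matrix <- cycle_generator(m)
  m
}

#' @rdname promoter_models
#' @param alpha,beta Shape and rate parameter of the Gamma OFF waiting-time
#'   distribution (mean OFF time `alpha / beta` s).
#' @export
gamma_model <- function(k_off, alpha, beta) {
  stopifnot(k_off > 0, alpha > 0, beta > 0)
  structure(list(k_off = k_off, alpha = alpha, beta = beta),
            class = c("gamma_promoter", "promoter_model"))
}

#' @rdname promoter_models
#' @param firing_rate Poisson initiation rate `r` (1/s).
#' @param tau_block Time (s) a freshly initiated polymerase occupies the
#'   initiation site (one polymerase step, ~6 s).
#' @export
poisson_model <- function(firing_rate, tau_block = 6) {
  stopifnot(firing_rate > 0, tau_block > 0)
  r_eff <- 1 / (tau_block + 1 / firing_rate)
  structure(list(firing_rate = firing_rate, tau_block = tau_block,
                 r_eff = r_eff, p_on = tau_block * r_eff),
            class = c("poisson_promoter", "promoter_model"))
}

#' @export
print.promoter_model <- function(x, ...) {
  cat("promoter_model <", class(x)[1], ">\n", sep = "")
  p <- x[!vapply(x, is.matrix, logical(1))]
  p <- p[vapply(p, is.numeric, logical(1))]
  cat(paste0("  ", names(p), " = ",
             vapply(p, function(v) paste(signif(v, 4), collapse = ", "),
                    character(1)),
             collapse = "\n"), "\n")
  cat(sprintf("  P_on = %.4g\n", stationary_on_probability(x)))
  invisible(x)
}

# Continuous-time generator of the cycle chain; state 1 is ON, then OFF_1..OFF_K.
cycle_generator <- function(model) {
  K <- model$K
  Q <- matrix(0, K + 1, K + 1)
  Q[1, 1] <- -model$k_off
  Q[1, 2] <- model$k_off
  for (m in seq_len(K)) {
    nxt <- if (m < K) m + 2 else 1
    Q[m + 1, m + 1] <- -model$off_rates[m]
    Q[m + 1, nxt] <- model$off_rates[m]
  }
  Q
}

#' Stationary ON probability of a promoter model
#'
#' Two-state: `k_on / (k_on + k_off)`. Cycle: the ON fraction of the mean
#' renewal period, `(1/k_off) / (1/k_off + sum_m 1/k_m)`. Gamma:
#' `(1 + alpha * k_off / beta)^-1`. Poisson-like: the fraction of time the
#' initiation site is occupied, `tau_block * r_eff`.
#'
#' @param model A `promoter_model`.
#' @return Probability in (0, 1).
#' @export
stationary_on_probability <- function(model) {
  UseMethod("stationary_on_probability")
}

#' @export
stationary_on_probability.two_state <- function(model) {
  model$k_on / (model$k_on + model$k_off)
}

#' @export
stationary_on_probability.cycle <- function(model) {
  ton <- 1 / model$k_off
  ton / (ton + sum(1 / model$off_rates))
}

#' @export
stationary_on_probability.gamma_promoter <- function(model) {
  1 / (1 + model$alpha * model$k_off / model$beta)
}

#' @export
stationary_on_probability.poisson_promoter <- function(model) {
  model$p_on
}

#' Effective ON-switching rate of a cycle model
#'
#' The inverse of the mean total OFF dwell time,
#' `k_on_eff = (sum_m 1/k_m)^-1`; equals `k_on` when K = 1.
#'
#' @param model A [cycle_model()] (a two-state model is accepted and returns
#'   its `k_on`).
#' @return Rate in 1/s.
#' @export
effective_on_rate <- function(model) {
  if (inherits(model, "two_state")) return(model$k_on)
  stopifnot(inherits(model, "cycle"))
  1 / sum(1 / model$off_rates)
}

#' Gamma OFF waiting-time density
#'
#' @param model A [gamma_model()].
#' @param t Waiting times (s), `t >= 0`.
#' @return Density values; mean of the distribution is `alpha / beta`.
#' @export
gamma_waiting_pdf <- function(model, t) {
  stopifnot(inherits(model, "gamma_promoter"), all(t >= 0))
  stats::dgamma(t, shape = model$alpha, rate = model$beta)
}

#' ON-ON propagator
#'
#' `A(n)`: probability that the promoter is ON at lag `n` polymerase steps
#' given that it was ON at lag 0 (stationary start within an ON period).
#' `A(0) = 1` and `A(n) -> P_on` as `n -> Inf`.
#'
#' Two-state: `A(n) = P_on + (1 - P_on) e^{(delta - 1) n}` with
#' `delta = 1 - (k_on + k_off) * step_time` (the continuous-time form; the
#' exact discrete chain gives `delta^n`, which agrees to second order in the
#' per-step rates). Cycle: the (ON, ON) entry of the matrix exponential of
#' the chain generator. Gamma: numerical inversion of the renewal-theory
#' Laplace transform `[k_off + s - k_off (1 + s/beta)^-alpha]^-1`.
#' Poisson-like: `A(n) = P_on` for every `n >= 1` (uncorrelated firing).
#'
#' @param model A `promoter_model`.
#' @param n Lag(s) in polymerase steps (may be fractional, `n >= 0`).
#' @param step_time_s Seconds per polymerase step.
#' @return Vector of probabilities.
#' @export
on_on_propagator <- function(model, n, step_time_s = 6) {
  if (any(n < 0)) stop("lag n must be >= 0")
  propagator_seconds(model, n * step_time_s)
}

# A(t) with t in seconds; internal generic shared by the correlation module.
propagator_seconds <- function(model, t_s) UseMethod("propagator_seconds")

#' @export
propagator_seconds.two_state <- function(model, t_s) {
  pon <- stationary_on_probability(model)
  pon + (1 - pon) * exp(-(model$k_on + model$k_off) * t_s)
}

#' @export
propagator_seconds.cycle <- function(model, t_s) {
  Q <- model$transition_matrix
  eg <- eigen(Q)
  co <- tryCatch(eg$vectors[1, ] * solve(eg$vectors)[, 1],
                 error = function(e) NULL)
  if (is.null(co)) {  # defective generator: nudge rates off the degeneracy
    m2 <- cycle_model(model$k_off * (1 + 1e-8),
                      model$off_rates * (1 + 1e-8 * seq_along(model$off_rates)))
    return(propagator_seconds(m2, t_s))
  }
  a <- Re(exp(outer(t_s, eg$values)) %*% co)
  pmin(pmax(as.numeric(a), 0), 1)
}

#' @export
propagator_seconds.poisson_promoter <- function(model, t_s) {
  ifelse(t_s == 0, 1, model$p_on)
}

#' @export
propagator_seconds.gamma_promoter <- function(model, t_s) {
  gamma_propagator(t_s, model$k_off, model$alpha, model$beta)
}

# Numerical inversion of the Gamma-model ON-ON propagator.
#
# The Laplace transform of A(t) for an alternating renewal process with
# exponential(k_off) ON and Gamma(alpha, beta) OFF dwell times is
#   h(s) = 1 / (k_off + s - k_off * (1 + s/beta)^-alpha).
# The even extension of A(|t|) - P_on has Fourier transform 2 Re h(i w).
# A Lorentzian with the matched rate lam = k_off + beta/alpha (so that
# (1 - P_on) lam = k_off) is inverted analytically and subtracted from the
# integrand, which then decays ~ w^-3; the remainder is integrated by the
# trapezoidal rule with the frequency cutoff extended until the integrand
# tail is < 1e-6 of its peak.
gamma_propagator <- function(t_s, k_off, alpha, beta, tol = 1e-6) {
  pon <- 1 / (1 + alpha * k_off / beta)
  lam <- k_off + beta / alpha
  g <- function(w) {
    h <- 1 / (k_off + 1i * w - k_off * (1 + 1i * w / beta)^(-alpha))
    2 * Re(h) - 2 * (1 - pon) * lam / (lam^2 + w^2)
  }
  # value at w = 0 from the series expansion of h about s = 0
  b2 <- k_off * alpha * (alpha + 1) / (2 * beta^2)
  g0 <- 2 * b2 * pon^2 - 2 * (1 - pon) / lam
  tmax <- max(t_s, 1 / lam)
  dw <- min(lam / 40, 2 * pi / (40 * tmax))
  wmax <- 50 * lam
  repeat {
    w <- seq(0, wmax, by = dw)
    gv <- g(w)
    gv[1] <- g0
    peak <- max(abs(gv))
    ntail <- max(2L, ceiling(0.02 * length(w)))
    if (max(abs(utils::tail(gv, ntail))) < tol * peak || wmax > 1e5 * lam)
      break
    wmax <- 2 * wmax
  }
  trap_w <- rep(dw, length(w))
  trap_w[c(1, length(w))] <- dw / 2
  gvw <- gv * trap_w
  corr <- vapply(t_s, function(tt) sum(gvw * cos(w * tt)) / pi, numeric(1))
  a <- pon + (1 - pon) * exp(-lam * abs(t_s)) + corr
  pmin(pmax(a, 0), 1)
}
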