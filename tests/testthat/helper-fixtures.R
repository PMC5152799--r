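# Shared fixtures and independent oracles for the test suite.

# Brute-force loop-function sum: walk every site and accumulate.
oracle_loop_sum <- function(construct) {
  L <- numeric(0)
  slope <- if (construct$loops_total > 0)
    construct$loops_total / construct$cassette_steps else 0
  for (i in seq_len(construct$pre_cassette_steps)) L <- c(L, 0)
  for (i in seq_len(construct$cassette_steps)) L <- c(L, slope * i)
  for (i in seq_len(construct$post_cassette_steps))
    L <- c(L, construct$loops_total)
  sum(L)
}

# Exact discrete-chain ON-ON propagator for the telegraph model: matrix
# power of the per-step transition matrix (the delta^n form).
oracle_discrete_propagator <- function(k_on_step, k_off_step, n) {
  P <- matrix(c(1 - k_off_step, k_off_step,
                k_on_step, 1 - k_on_step), 2, 2, byrow = TRUE)
  M <- diag(2)
  for (i in seq_len(n)) M <- M %*% P
  M[1, 1]
}

# Full cycle-chain propagator matrix at time t (eigen oracle, all entries).
oracle_cycle_propagator_matrix <- function(model, t_s) {
  eg <- eigen(model$transition_matrix)
  Re(eg$vectors %*% diag(exp(eg$values * t_s), nrow = length(eg$values)) %*%
       solve(eg$vectors))
}

# A small trace_set built from explicit vectors.
make_traces <- function(values, dt = 6, ...) {
  if (is.numeric(values)) values <- list(values)
  tt <- lapply(values, function(v) (seq_along(v) - 1) * dt)
  trace_set(values, tt, meta = data.frame(...))
}

# Mean-subtracted per-trace autocovariance averaged over traces: the raw
# numerator whose expectation finite_trace_correction() computes.
raw_mean_subtracted_autocov <- function(traces, max_lag) {
  vs <- msburst:::steady_values(traces)
  num <- sapply(vs, function(v) {
    x <- v - mean(v); K <- length(v)
    vapply(0:max_lag, function(r) {
      i <- seq_len(K - r); mean(x[i] * x[i + r])
    }, numeric(1))
  })
  rowMeans(num)
}

std_construct <- construct_3prime()
std_loops <- build_loop_function(std_construct)
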