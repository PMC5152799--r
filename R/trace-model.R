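#' Fluorescence produced by a promoter state history
#'
#' Maps a binary promoter occupation trace X (one value per polymerase step,
#' X = 1 when a polymerase occupies the initiation site) to the observable
#' fluorescence in loop units: `F(t) = sum_i L[i] * X(t - i)`. Each polymerase
#' that initiated at step `t - i` sits at site `i` at step `t` and carries
#' `L[i]` loops.
#'
#' The first `r` steps (r = length of the loop function) are a loading
#' transient during which the gene is not yet fully populated; they are
#' reported but flagged, and steady-state analyses should drop them.
#'
#' @param states Integer/logical vector of promoter states on the polymerase
#'   step grid (0 = OFF-class, 1 = ON).
#' @param loop_fn Loop function from [build_loop_function()].
#' @return Numeric vector `F` of the same length as `states`, with attribute
#'   `transient`: logical vector, `TRUE` for the warm-up steps `t < r`.
#' @export
fluorescence_from_states <- function(states, loop_fn) {
  states <- as.numeric(states)
  if (length(states) < 1) stop("states must have length >= 1")
  if (any(!states %in% c(0, 1))) stop("states must be binary (0/1)")
  L <- as.numeric(loop_fn)
  r <- length(L)
  n <- length(states)
  # F[t] = sum_{i=1..r} L[i] * X[t - i]; X before the recording starts is 0
  xpad <- c(numeric(r), states)
  f <- numeric(n)
  for (i in seq_len(r)) f <- f + L[i] * xpad[(r - i) + seq_len(n)]
  attr(f, "transient") <- seq_len(n) <= r
  f
}

#' Mean steady-state fluorescence
#'
#' `<F> = P_on * sum_i L[i]` : the stationary ON probability times the
#' saturation fluorescence of a fully loaded gene.
#'
#' @param p_on Stationary probability that the promoter is ON, in `[0, 1]`.
#' @param loop_fn Loop function.
#' @return Mean fluorescence in loop units.
#' @export
mean_fluorescence <- function(p_on, loop_fn) {
  if (!is.numeric(p_on) || any(p_on < 0 | p_on > 1))
    stop("p_on must lie in [0, 1]")
  p_on * sum(as.numeric(loop_fn))
}
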