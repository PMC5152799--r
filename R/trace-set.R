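#' A collection of single-locus fluorescence time traces
#'
#' Container for per-nucleus spot-intensity time series with metadata. Each
#' trace is a numeric series on a uniform time grid; different embryos may
#' use different sampling intervals. A logical steady-state mask per trace
#' marks the plateau window used by all steady-state analyses.
#'
#' @param intensity List of numeric vectors (one per trace), or a single
#'   numeric vector for one trace.
#' @param time_s List of numeric vectors of time stamps (s), matching
#'   `intensity`.
#' @param meta Data frame with one row per trace; columns `embryo_id`,
#'   `cycle`, `nucleus_id` and optionally `ap_position` (fraction of egg
#'   length, anterior = 0) and `mother_id`. Defaults are filled in.
#' @param steady Optional list of logical vectors marking the steady-state
#'   samples of each trace; defaults to all `TRUE`.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(intensity, time_s, meta = NULL, steady = NULL) {
  if (is.numeric(intensity)) intensity <- list(intensity)
  if (is.numeric(time_s)) time_s <- list(time_s)
  M <- length(intensity)
  stopifnot(length(time_s) == M, M >= 1)
  for (i in seq_len(M)) {
    stopifnot(length(intensity[[i]]) == length(time_s[[i]]))
    if (any(!is.finite(intensity[[i]]))) stop("intensities must be finite")
    dtv <- diff(time_s[[i]])
    if (length(dtv) &&
        any(abs(dtv - stats::median(dtv)) > 1e-6 * stats::median(dtv)))
      stop("trace ", i, " is not on a uniform time grid")
  }
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(M))
  meta <- as.data.frame(meta)
  if (nrow(meta) == 0 && M > 0) meta <- data.frame(row.names = seq_len(M))
  stopifnot(nrow(meta) == M)
  if (is.null(meta$embryo_id)) meta$embryo_id <- 1L
  if (is.null(meta$cycle)) meta$cycle <- NA_integer_
  if (is.null(meta$nucleus_id)) meta$nucleus_id <- seq_len(M)
  if (is.null(meta$ap_position)) meta$ap_position <- NA_real_
  if (is.null(meta$mother_id)) meta$mother_id <- NA_integer_
  meta$dt_s <- vapply(time_s, function(t)
    if (length(t) > 1) stats::median(diff(t)) else NA_real_, numeric(1))
  if (is.null(steady)) steady <- lapply(intensity, function(v) rep(TRUE, length(v)))
  stopifnot(length(steady) == M)
  neg <- vapply(intensity, function(v) any(v < 0), logical(1))
  structure(list(intensity = intensity, time_s = time_s, meta = meta,
                 steady = steady, has_negative = neg),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  k <- lengths(x$intensity)
  cat(sprintf("trace_set: %d traces, %d-%d samples, dt %s s, %d embryo(s)\n",
              length(x$intensity), min(k), max(k),
              paste(signif(sort(unique(x$meta$dt_s)), 3), collapse = "/"),
              length(unique(x$meta$embryo_id))))
  invisible(x)
}

#' Number of traces in a trace set
#' @param traces A [trace_set()].
#' @return Integer count.
#' @export
n_traces <- function(traces) length(traces$intensity)

#' Subset a trace set
#'
#' @param traces A [trace_set()].
#' @param idx Integer or logical index over traces, or `NULL`.
#' @param embryo,cycle,region Optional filters; `region` is matched against
#'   [classify_region()] of the nucleus position.
#' @return A [trace_set()].
#' @export
subset_traces <- function(traces, idx = NULL, embryo = NULL, cycle = NULL,
                          region = NULL) {
  keep <- rep(TRUE, n_traces(traces))
  if (!is.null(embryo)) keep <- keep & traces$meta$embryo_id %in% embryo
  if (!is.null(cycle)) keep <- keep & traces$meta$cycle %in% cycle
  if (!is.null(region))
    keep <- keep & classify_region(traces$meta$ap_position) %in% region
  keep <- which(keep)
  if (!is.null(idx)) keep <- keep[idx] else keep <- keep
  if (length(keep) == 0) stop("no traces left after subsetting")
  trace_set(traces$intensity[keep], traces$time_s[keep],
            traces$meta[keep, setdiff(names(traces$meta), "dt_s"),
                        drop = FALSE],
            traces$steady[keep])
}

#' Rescale all intensities (e.g. by a calibration factor)
#' @param traces A [trace_set()].
#' @param factor Multiplicative factor.
#' @return A [trace_set()].
#' @export
scale_traces <- function(traces, factor) {
  traces$intensity <- lapply(traces$intensity, function(v) v * factor)
  traces
}

# Steady-state portions as plain numeric vectors (internal).
steady_values <- function(traces) {
  mapply(function(v, s) v[s], traces$intensity, traces$steady,
         SIMPLIFY = FALSE)
}

# Common sampling interval of a set; errors if traces mix intervals.
common_dt <- function(traces) {
  dt <- unique(round(traces$meta$dt_s, 9))
  if (length(dt) != 1)
    stop("traces mix sampling intervals (", paste(dt, collapse = ", "),
         " s); subset per embryo first")
  dt
}
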