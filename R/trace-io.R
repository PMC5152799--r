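#' Read / write trace tables
#'
#' Traces travel as delimited text (comma or tab, autodetected) in long
#' format with one row per nucleus per time point. Required columns:
#' `embryo_id`, `cycle`, `nucleus_id`, `time_s`, `intensity`; optional:
#' `ap_position` (fraction of egg length), `mother_id`. Rows may arrive in
#' any order; each trace must sit on a uniform time grid (per embryo the
#' sampling interval is constant, but embryos may differ).
#'
#' @param path File path.
#' @param grid_tol Relative tolerance on time-grid uniformity.
#' @return `read_traces` returns a [trace_set()]; `write_traces` invisibly
#'   returns `path`.
#' @export
read_traces <- function(path, grid_tol = 1e-3) {
  if (!file.exists(path)) stop("no such file: ", path)
  l1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", l1)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("embryo_id", "cycle", "nucleus_id", "time_s", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$ap_position)) df$ap_position <- NA_real_
  if (is.null(df$mother_id)) df$mother_id <- NA_integer_
  df <- df[order(df$embryo_id, df$cycle, df$nucleus_id, df$time_s), ]
  key <- paste(df$embryo_id, df$cycle, df$nucleus_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  intensity <- lapply(idx, function(i) df$intensity[i])
  time_s <- lapply(idx, function(i) df$time_s[i])
  for (i in seq_along(time_s)) {
    dtv <- diff(time_s[[i]])
    if (length(dtv) > 1) {
      md <- stats::median(dtv)
      if (any(abs(dtv - md) > grid_tol * md))
        stop("non-uniform time grid in trace ", names(idx)[i],
             " beyond tolerance; missing samples?")
    }
  }
  first <- vapply(idx, `[`, numeric(1), 1)
  meta <- data.frame(embryo_id = df$embryo_id[first],
                     cycle = df$cycle[first],
                     nucleus_id = df$nucleus_id[first],
                     ap_position = df$ap_position[first],
                     mother_id = df$mother_id[first])
  ts <- trace_set(unname(intensity), unname(time_s), meta)
  if (any(ts$has_negative))
    message(sum(ts$has_negative),
            " trace(s) contain small negative intensities",
            " (background-subtracted data); flagged, not altered")
  ts
}

#' @rdname read_traces
#' @param traces A [trace_set()].
#' @param sep Field separator (`","` or `"\t"`).
#' @export
write_traces <- function(traces, path, sep = ",") {
  utils::write.table(as.data.frame(traces), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  m <- x$meta
  do.call(rbind, lapply(seq_along(x$intensity), function(i)
    data.frame(embryo_id = m$embryo_id[i], cycle = m$cycle[i],
               nucleus_id = m$nucleus_id[i], time_s = x$time_s[[i]],
               intensity = x$intensity[[i]],
               ap_position = m$ap_position[i],
               mother_id = m$mother_id[i])))
}

#' Select the steady-state expression window
#'
#' Expression within one interphase ramps up after mitotic reactivation,
#' plateaus, and shuts down before the next mitosis; only the plateau
#' reflects stationary promoter switching. Per embryo and cell cycle the
#' ensemble-mean intensity over all traces is smoothed with a centred
#' moving average and the window is bounded by the first and last crossing
#' of `plateau_fraction` of the cycle's maximum.
#'
#' @param traces A [trace_set()].
#' @param plateau_fraction Fraction of the smoothed maximum that defines the
#'   plateau (default 0.8).
#' @param smooth_width Moving-average width in samples (odd, default 3).
#' @return Data frame of windows (`embryo_id`, `cycle`, `start_s`, `end_s`,
#'   `n_samples`). Errors if a group never reaches a plateau (monotone
#'   ramp): pass explicit bounds to [mark_steady_state()] instead.
#' @export
select_steady_state <- function(traces, plateau_fraction = 0.8,
                                smooth_width = 3) {
  m <- traces$meta
  groups <- unique(m[, c("embryo_id", "cycle")])
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    sel <- which(m$embryo_id == groups$embryo_id[g] &
                   (m$cycle == groups$cycle[g] |
                      (is.na(m$cycle) & is.na(groups$cycle[g]))))
    tt <- sort(unique(unlist(traces$time_s[sel])))
    if (length(tt) < 5) stop("need at least 5 time points per group")
    acc <- cnt <- numeric(length(tt))
    for (i in sel) {
      j <- match(traces$time_s[[i]], tt)
      acc[j] <- acc[j] + traces$intensity[[i]]
      cnt[j] <- cnt[j] + 1
    }
    mu <- acc / pmax(cnt, 1)
    if (smooth_width > 1) {
      k <- smooth_width %/% 2L
      sm <- as.numeric(stats::filter(mu, rep(1 / (2 * k + 1), 2 * k + 1),
                                     sides = 2))
      sm[is.na(sm)] <- mu[is.na(sm)]
    } else sm <- mu
    thr <- plateau_fraction * max(sm)
    above <- which(sm >= thr)
    # a mean still rising through the end of the cycle never plateaued
    ramp_like <- max(above) == length(tt) &&
      all(diff(sm[above]) > 1e-9 * max(sm))
    if (length(above) < 2 || ramp_like)
      stop("no expression plateau found for embryo ",
           groups$embryo_id[g], " cycle ", groups$cycle[g],
           "; supply manual bounds via mark_steady_state()")
    out <- rbind(out, data.frame(embryo_id = groups$embryo_id[g],
                                 cycle = groups$cycle[g],
                                 start_s = tt[min(above)],
                                 end_s = tt[max(above)],
                                 n_samples = length(above)))
  }
  out
}

#' Mark steady-state samples of a trace set
#'
#' Applies windows (from [select_steady_state()] or chosen manually) to the
#' per-trace steady-state masks used by all downstream analyses.
#'
#' @param traces A [trace_set()].
#' @param windows Data frame with `embryo_id`, `cycle`, `start_s`, `end_s`;
#'   or a numeric `c(start_s, end_s)` applied to every trace.
#' @return The [trace_set()] with updated masks.
#' @export
mark_steady_state <- function(traces, windows) {
  if (is.numeric(windows))
    windows <- data.frame(embryo_id = NA, cycle = NA,
                          start_s = windows[1], end_s = windows[2])
  m <- traces$meta
  for (i in seq_len(n_traces(traces))) {
    w <- windows
    if (!all(is.na(windows$embryo_id)))
      w <- windows[windows$embryo_id == m$embryo_id[i] &
                     (windows$cycle == m$cycle[i] |
                        (is.na(windows$cycle) & is.na(m$cycle[i]))), ]
    if (nrow(w) == 0) { traces$steady[[i]][] <- FALSE; next }
    traces$steady[[i]] <- traces$time_s[[i]] >= w$start_s[1] &
      traces$time_s[[i]] <= w$end_s[1]
  }
  traces
}

#' Classify a nucleus position on the anterior-posterior axis
#'
#' Anterior: 0-35% egg length (high expression); boundary: 45-55% egg
#' length (where expression falls); other positions are unclassified. The
#' embryo midpoint sits at 50% egg length.
#'
#' @param ap_position Position(s) as fraction of egg length in `[0, 1]`
#'   (anterior = 0). `NA` passes through as `NA`.
#' @return Character vector: `"anterior"`, `"boundary"` or
#'   `"unclassified"`.
#' @export
classify_region <- function(ap_position) {
  bad <- !is.na(ap_position) & (ap_position < 0 | ap_position > 1)
  if (any(bad)) stop("ap_position outside [0, 1]")
  ifelse(is.na(ap_position), NA_character_,
         ifelse(ap_position <= 0.35, "anterior",
                ifelse(ap_position >= 0.45 & ap_position <= 0.55,
                       "boundary", "unclassified")))
}
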