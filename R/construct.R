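#' Describe an MS2 reporter gene construct
#'
#' A construct is discretised into polymerase-sized sites of `step_bp` base
#' pairs (150 bp, the footprint of one polymerase). A polymerase advances one
#' site per `step_time_s` seconds, so the gene holds at most
#' `pre_cassette_steps + cassette_steps + post_cassette_steps` polymerases at
#' a time. The MS2 stem-loop cassette spans `cassette_steps` sites and carries
#' `loops_total` loops.
#'
#' @param pre_cassette_steps Integer, polymerase steps upstream of the first
#'   MS2 loop (0 for a 5' cassette).
#' @param cassette_steps Integer, polymerase steps spanned by the MS2 cassette.
#' @param post_cassette_steps Integer, polymerase steps downstream of the last
#'   loop (0 for a 3' cassette).
#' @param loops_total Number of MS2 loops in the cassette (24 in the standard
#'   reporter).
#' @param step_bp Base pairs per polymerase step (default 150).
#' @param step_time_s Seconds per polymerase step (the promoter blocking time
#'   tau_block, default 6 s).
#' @return An object of class `gene_construct`.
#' @examples
#' # 24-loop cassette at the extreme 3' end: ~2 loops per step
#' gc3 <- gene_construct(pre_cassette_steps = 12, cassette_steps = 12,
#'                       post_cassette_steps = 0, loops_total = 24)
#' buffering_time(gc3)  # 72 s
#' @export
gene_construct <- function(pre_cassette_steps, cassette_steps,
                           post_cassette_steps, loops_total = 24,
                           step_bp = 150, step_time_s = 6) {
  pre  <- as.integer(round(pre_cassette_steps))
  cas  <- as.integer(round(cassette_steps))
  post <- as.integer(round(post_cassette_steps))
  if (any(c(pre, cas, post) < 0))
    stop("step counts must be non-negative")
  if (loops_total < 0) stop("loops_total must be non-negative")
  if (loops_total >= 1 && cas < 1)
    stop("invalid construct: loops_total >= 1 requires cassette_steps >= 1")
  if (pre + cas + post < 1) stop("construct must span at least one site")
  if (step_bp <= 0 || step_time_s <= 0)
    stop("step_bp and step_time_s must be positive")
  step_bp <- as.numeric(step_bp)
  step_time_s <- as.numeric(step_time_s)
  structure(list(pre_cassette_steps = pre, cassette_steps = cas,
                 post_cassette_steps = post, loops_total = loops_total,
                 step_bp = step_bp, step_time_s = step_time_s),
            class = "gene_construct")
}

#' @export
print.gene_construct <- function(x, ...) {
  r <- x$pre_cassette_steps + x$cassette_steps + x$post_cassette_steps
  cat(sprintf(
    "gene_construct: %d sites (%d pre / %d cassette / %d post), %g loops, %g bp and %g s per step\n",
    r, x$pre_cassette_steps, x$cassette_steps, x$post_cassette_steps,
    x$loops_total, x$step_bp, x$step_time_s))
  invisible(x)
}

#' Read a construct description from a YAML or JSON config file
#'
#' The file gives lengths in base pairs (`pre_cassette_bp`, `cassette_bp`,
#' `post_cassette_bp`) plus `loops_total` and optionally `step_bp`,
#' `step_time_s`. Base-pair lengths are converted to polymerase steps by
#' rounding to the nearest integer step.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A [gene_construct()].
#' @export
read_construct <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("pre_cassette_bp", "cassette_bp", "post_cassette_bp", "loops_total")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("construct config missing keys: ", paste(miss, collapse = ", "))
  step_bp <- if (is.null(cfg$step_bp)) 150 else cfg$step_bp
  step_time_s <- if (is.null(cfg$step_time_s)) 6 else cfg$step_time_s
  gene_construct(pre_cassette_steps = round(cfg$pre_cassette_bp / step_bp),
                 cassette_steps = round(cfg$cassette_bp / step_bp),
                 post_cassette_steps = round(cfg$post_cassette_bp / step_bp),
                 loops_total = cfg$loops_total,
                 step_bp = step_bp, step_time_s = step_time_s)
}

#' Loop function of a construct
#'
#' `L[i]` is the cumulative number of MS2 loops transcribed by a polymerase
#' that has reached site `i` (i = 1..r). It is zero before the cassette, a
#' linear ramp of slope `loops_total / cassette_steps` across the cassette
#' (loop counts need not be integers because polymerase and loop lengths do
#' not coincide) and saturates at `loops_total` after the cassette.
#'
#' @param construct A [gene_construct()].
#' @return Numeric vector of length r with class `loop_function`.
#' @export
build_loop_function <- function(construct) {
  stopifnot(inherits(construct, "gene_construct"))
  pre <- construct$pre_cassette_steps
  cas <- construct$cassette_steps
  post <- construct$post_cassette_steps
  r <- pre + cas + post
  L <- numeric(r)
  if (construct$loops_total > 0) {
    slope <- construct$loops_total / cas
    if (cas > 0) L[pre + seq_len(cas)] <- slope * seq_len(cas)
    if (post > 0) L[pre + cas + seq_len(post)] <- construct$loops_total
  }
  structure(L, class = c("loop_function", class(L)),
            step_time_s = construct$step_time_s)
}

#' Minimal buffering time of a construct
#'
#' Time for a polymerase to traverse the loop-carrying part of the gene
#' (cassette plus downstream sequence): the probe's intrinsic correlation
#' time. Equals `(cassette_steps + post_cassette_steps) * step_time_s`.
#'
#' @param construct A [gene_construct()].
#' @return Buffering time in seconds.
#' @export
buffering_time <- function(construct) {
  stopifnot(inherits(construct, "gene_construct"))
  (construct$cassette_steps + construct$post_cassette_steps) *
    construct$step_time_s
}

#' The 24-loop 3' reporter used throughout the examples
#'
#' 24 MS2 loops over 12 polymerase steps (about two loops per 150-bp step)
#' at the extreme 3' end of a gene with 12 upstream steps.
#'
#' @param step_time_s Seconds per polymerase step.
#' @return A [gene_construct()].
#' @export
construct_3prime <- function(step_time_s = 6) {
  gene_construct(12, 12, 0, loops_total = 24, step_time_s = step_time_s)
}

#' A 5' variant: same cassette followed by 3000 bp of non-binding sequence
#' @param step_time_s Seconds per polymerase step.
#' @return A [gene_construct()].
#' @export
construct_5prime <- function(step_time_s = 6) {
  gene_construct(0, 12, 20, loops_total = 24, step_time_s = step_time_s)
}
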