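## Coverage analysis over the ribosomal DNA repeat unit, handled as a
## named auxiliary reference span (coordinates unit-relative) rather than
## physically spliced into a chromosome.  Pipeline: exact-duplicate read
## removal, per-bp depth, input subtraction (library-size scaled by
## default), and non-overlapping fixed-width window means.

#' Remove exact duplicate reads
#'
#' Keeps the first occurrence of each exact sequence (case-sensitive),
#' preserving order otherwise.  Idempotent.
#'
#' @param sequences Character vector of read sequences.
#' @return List with `sequences` (deduplicated) and `n_removed`.
#' @export
dedup_reads <- function(sequences) {
  dup <- duplicated(sequences)
  list(sequences = sequences[!dup], n_removed = sum(dup))
}

#' Per-basepair coverage over a reference span
#'
#' `depth[i]` is the number of reads whose alignment covers base `i` of
#' the span.
#'
#' @param records Data frame with `pos` (1-based leftmost) and `read_len`
#'   (reference span), e.g. from [read_sam_records()], or a `GRanges`.
#' @param span_length Length of the reference span in bp.
#' @return Numeric vector of length `span_length`.
#' @export
coverage_track <- function(records, span_length) {
  if (methods::is(records, "GRanges")) {
    ir <- IRanges::ranges(records)
  } else {
    ir <- IRanges::IRanges(records$pos, width = records$read_len)
  }
  if (length(ir) && (min(BiocGenerics::start(ir)) < 1 ||
                     max(BiocGenerics::end(ir)) > span_length))
    stop("record outside the reference span")
  as.numeric(IRanges::coverage(ir, width = span_length))
}

#' Subtract input coverage from ChIP coverage
#'
#' With `scale = "per_million"` both tracks are first converted to
#' reads-per-million using the supplied library sizes (defaulting to the
#' summed track when omitted); with `scale = "raw"` the tracks are
#' differenced as-is.  Negative values are retained.
#'
#' @param rdip_track,input_track Equal-length numeric per-bp tracks.
#' @param scale `"per_million"` or `"raw"`.
#' @param rdip_lib,input_lib Library sizes (total aligned reads) used for
#'   per-million scaling.
#' @return Numeric track of the same length.
#' @export
input_subtract <- function(rdip_track, input_track,
                           scale = c("per_million", "raw"),
                           rdip_lib = NULL, input_lib = NULL) {
  scale <- match.arg(scale)
  if (length(rdip_track) != length(input_track))
    stop("track spans differ")
  if (scale == "per_million") {
    if (is.null(rdip_lib)) rdip_lib <- sum(rdip_track)
    if (is.null(input_lib)) input_lib <- sum(input_track)
    if (rdip_lib <= 0 || input_lib <= 0)
      stop("library sizes must be positive for per-million scaling")
    rdip_track <- rdip_track / rdip_lib * 1e6
    input_track <- input_track / input_lib * 1e6
  }
  rdip_track - input_track
}

#' Means of a per-bp track over non-overlapping windows
#'
#' The terminal partial window is averaged over its true width.
#'
#' @param track Numeric per-bp vector.
#' @param width Window width in bp (default 50).
#' @return `data.frame` with `start` (0-based), `end`, `mean`.
#' @export
window_mean <- function(track, width = 50) {
  if (width <= 0) stop("width must be > 0")
  n <- length(track)
  if (n == 0) return(data.frame(start = numeric(), end = numeric(),
                                mean = numeric()))
  idx <- rep(seq_len(ceiling(n / width)), each = width, length.out = n)
  means <- as.numeric(tapply(track, idx, mean))
  start <- (seq_along(means) - 1) * width
  data.frame(start = start, end = pmin(start + width, n), mean = means)
}

#' Input-normalized windowed rDNA signal
#'
#' Convenience wrapper: coverage of RDIP and input records over the rDNA
#' unit, input subtraction, then window means.
#'
#' @param rdip_records,input_records Alignment record frames on the unit.
#' @param span_length Length of the rDNA unit (bp).
#' @param width Window width (default 50).
#' @param scale Passed to [input_subtract()].
#' @return `data.frame` from [window_mean()] of the normalized track.
#' @export
rdna_profile <- function(rdip_records, input_records, span_length,
                         width = 50, scale = "per_million") {
  rd <- coverage_track(rdip_records, span_length)
  inp <- coverage_track(input_records, span_length)
  window_mean(input_subtract(rd, inp, scale = scale), width = width)
}
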