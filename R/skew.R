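## Nucleotide-composition statistics.  Skews are computed on the top
## (forward) reference strand with the standard definitions
##   AT skew = (A - T) / (A + T),  GC skew = (G - C) / (G + C),
## and the purine fraction is (G + A) / (A + C + G + T).  N bases never
## enter a denominator.  Under reverse complement both skews negate and
## purine fractions of a sequence and its complement sum to 1.

#' Count bases in a sequence
#'
#' @param sequence Character string or `DNAString` over `{A,C,G,T,N}`,
#'   case-insensitive.
#' @return Named integer vector with elements A, C, G, T, N.
#' @export
base_counts <- function(sequence) {
  if (methods::is(sequence, "DNAString"))
    sequence <- as.character(sequence)
  if (length(sequence) != 1) stop("one sequence at a time")
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0)
    stop("invalid base '", substring(sequence, bad, bad),
         "' at offset ", bad)
  if (!nzchar(sequence))
    return(c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L))
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                     c("A", "C", "G", "T", "N"))
  stats::setNames(as.integer(cnt), c("A", "C", "G", "T", "N"))
}

skew_from_counts <- function(cnt) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  inf <- cnt[["A"]] + cnt[["C"]] + cnt[["G"]] + cnt[["T"]]
  list(A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
       N = cnt[["N"]],
       at_skew = rat(cnt[["A"]] - cnt[["T"]], cnt[["A"]] + cnt[["T"]]),
       gc_skew = rat(cnt[["G"]] - cnt[["C"]], cnt[["G"]] + cnt[["C"]]),
       purine_fraction = rat(cnt[["G"]] + cnt[["A"]], inf))
}

#' Skew statistics of a sequence
#'
#' @inheritParams base_counts
#' @return A one-row `data.frame` with the base counts, `at_skew`,
#'   `gc_skew`, and `purine_fraction`.  Statistics with a zero denominator
#'   are `NA`, not 0.
#' @examples
#' skew_stats("GGAATC")  # purine fraction 4/6
#' @export
skew_stats <- function(sequence) {
  as.data.frame(skew_from_counts(base_counts(sequence)))
}

peak_sequences <- function(peaks, genome) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  validate_intervals(peaks, genome)
  out <- Biostrings::subseq(
    genome$sequence[as.character(GenomeInfoDb::seqnames(peaks))],
    start = BiocGenerics::start(peaks), end = BiocGenerics::end(peaks))
  names(out) <- NULL
  out
}

#' Skew statistics on the called RNA strand of each peak
#'
#' Computes per-peak composition on the strand carrying the RNA of the
#' hybrid, as called by [strandedness_score()]: bottom-strand (`-`) calls
#' are reverse complemented first.  Ambiguous peaks are skipped and
#' counted.
#'
#' @param peaks `GRanges` with an `rna_strand` metadata column.
#' @param genome A [Genome] with sequence.
#' @return A `data.frame`, one row per non-ambiguous peak, with columns
#'   `peak` (index into `peaks`), base counts on the RNA strand, `at_skew`,
#'   `gc_skew`, `purine_fraction`, plus attribute `n_ambiguous`.
#' @export
rna_strand_skew <- function(peaks, genome) {
  call <- S4Vectors::mcols(peaks)$rna_strand
  if (is.null(call)) stop("peaks carry no rna_strand calls")
  keep <- call %in% c("+", "-")
  seqs <- peak_sequences(peaks[keep], genome)
  flip <- call[keep] == "-"
  if (any(flip)) seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  rows <- lapply(seq_along(seqs), function(i)
    skew_from_counts(base_counts(seqs[[i]])))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(out)) out <- skew_stats("")[0, ]
  out <- cbind(peak = which(keep), rna_strand = call[keep], out)
  attr(out, "n_ambiguous") <- sum(!keep)
  out
}

#' Positional purine-fraction profile within peaks
#'
#' Each peak is oriented 5'->3' along its called RNA strand, rescaled to
#' unit length, and cut into `bins` equal pieces; the purine fraction of
#' each piece is averaged over peaks.  A 5' displacement of the
#' purine-enriched component shows up as a decreasing profile.
#'
#' @param peaks `GRanges` with `rna_strand` calls.
#' @param genome A [Genome] with sequence.
#' @param bins Number of bins (>= 2).
#' @return `data.frame` with columns `bin`, `mean_purine_fraction`, `n`;
#'   attribute `n_skipped` counts peaks shorter than `bins` or ambiguous.
#' @export
positional_skew_profile <- function(peaks, genome, bins = 10) {
  if (bins < 2) stop("bins must be >= 2")
  call <- S4Vectors::mcols(peaks)$rna_strand
  if (is.null(call)) stop("peaks carry no rna_strand calls")
  usable <- call %in% c("+", "-") & BiocGenerics::width(peaks) >= bins
  seqs <- peak_sequences(peaks[usable], genome)
  flip <- call[usable] == "-"
  if (any(flip)) seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  acc <- matrix(NA_real_, nrow = length(seqs), ncol = bins)
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    L <- nchar(s)
    edges <- floor(L * (0:bins) / bins)
    for (b in seq_len(bins)) {
      cnt <- base_counts(substring(s, edges[b] + 1, edges[b + 1]))
      inf <- sum(cnt[c("A", "C", "G", "T")])
      acc[i, b] <- if (inf > 0) (cnt[["G"]] + cnt[["A"]]) / inf else NA_real_
    }
  }
  out <- data.frame(bin = seq_len(bins),
                    mean_purine_fraction = colMeans(acc, na.rm = TRUE),
                    n = colSums(!is.na(acc)))
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Orientation bias of intragenic peaks
#'
#' Labels every peak overlapping a gene as sense (RNA strand equals the
#' gene strand) or antisense, and tests the split against 50:50 with a
#' two-sided binomial test.  Peaks overlapping several genes are assigned
#' to the gene with the largest overlap.
#'
#' @param peaks `GRanges` with `rna_strand` calls.
#' @param genes Stranded `GRanges` of genes.
#' @return List with `n_sense`, `n_antisense`, `p_value`, and the per-peak
#'   label vector (`NA` for intergenic or ambiguous peaks).
#' @export
gene_orientation_bias <- function(peaks, genes) {
  call <- S4Vectors::mcols(peaks)$rna_strand
  if (is.null(call)) stop("peaks carry no rna_strand calls")
  if (any(as.character(BiocGenerics::strand(genes)) == "*"))
    stop("genes must be stranded")
  hits <- GenomicRanges::findOverlaps(peaks, genes, ignore.strand = TRUE)
  ov <- BiocGenerics::width(IRanges::pintersect(
    peaks[S4Vectors::queryHits(hits)], genes[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  best <- tapply(seq_along(ov), S4Vectors::queryHits(hits),
                 function(i) i[which.max(ov[i])])
  qh <- S4Vectors::queryHits(hits)[unlist(best)]
  sh <- S4Vectors::subjectHits(hits)[unlist(best)]
  label <- rep(NA_character_, length(peaks))
  gs <- as.character(BiocGenerics::strand(genes))[sh]
  ok <- call[qh] %in% c("+", "-")
  label[qh[ok]] <- ifelse(call[qh[ok]] == gs[ok], "sense", "antisense")
  n_sense <- sum(label == "sense", na.rm = TRUE)
  n_anti <- sum(label == "antisense", na.rm = TRUE)
  p <- if (n_sense + n_anti > 0)
    stats::binom.test(n_sense, n_sense + n_anti, 0.5)$p.value else NA_real_
  list(n_sense = n_sense, n_antisense = n_anti, p_value = p, labels = label)
}
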