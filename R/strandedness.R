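## RNA-strand inference for directional RDIP-seq.
##
## The library protocol incorporates dUTP into the strand complementary to
## the RNA of the hybrid and degrades it with UNG before amplification, so
## the second read of each proper pair carries the RNA-derived sequence.
## In SAM terms that read has flag 163 (paired + proper + mate-reverse +
## second-in-pair) when it aligns to the top reference strand and 147
## (paired + proper + reverse + second-in-pair) when it aligns to the
## bottom strand.  Everything else (first-in-pair, discordant, secondary,
## duplicate, supplementary) is excluded from strand evidence.

#' SAM flags carrying RNA-strand evidence
#'
#' The flag of the properly paired second-in-pair read aligned to the top
#' (forward) or bottom (reverse) reference strand, composed from SAM
#' template bits via [sam_flag()].
#'
#' @return Named integer vector with elements `top` and `bottom`.
#' @examples
#' rna_evidence_flags()  # c(top = 163, bottom = 147)
#' @export
rna_evidence_flags <- function() {
  c(top = sam_flag(paired = TRUE, proper_pair = TRUE, mate_reverse = TRUE,
                   second_in_pair = TRUE),
    bottom = sam_flag(paired = TRUE, proper_pair = TRUE, reverse = TRUE,
                      second_in_pair = TRUE))
}

#' Classify the RNA-derived strand of alignment records
#'
#' @param flag Integer vector of SAM flags (or a data frame from
#'   [read_sam_records()], in which case its `flag` column is used).
#' @return Factor with levels `top`, `bottom`, `excluded`.
#' @examples
#' classify_rna_strand(c(163L, 147L, 99L, 4L))
#' @export
classify_rna_strand <- function(flag) {
  if (is.data.frame(flag)) flag <- flag$flag
  ref <- rna_evidence_flags()
  out <- rep("excluded", length(flag))
  out[flag == ref[["top"]]] <- "top"
  out[flag == ref[["bottom"]]] <- "bottom"
  factor(out, levels = c("top", "bottom", "excluded"))
}

records_to_granges <- function(records) {
  GenomicRanges::GRanges(records$chrom,
                         IRanges::IRanges(records$pos,
                                          width = pmax(records$read_len, 1)))
}

#' Score per-peak strandedness
#'
#' Counts the RNA-derived reads (flags 163/147) whose alignment overlaps
#' each peak by at least 1 bp and computes the strandedness score
#' `s = (n_top - n_bottom) / (n_top + n_bottom)`: +1 when every RNA-derived
#' read aligns to the top strand, -1 when every one aligns to the bottom
#' strand.  Peaks with no classified reads get `s = NA` and an `ambiguous`
#' call.
#'
#' @param peaks A `GRanges` of peaks.
#' @param records Data frame from [read_sam_records()].
#' @return `peaks` with metadata columns `n_top`, `n_bottom`,
#'   `strandedness`, and `rna_strand` (`+`, `-`, or `ambiguous`).
#' @export
strandedness_score <- function(peaks, records) {
  cls <- classify_rna_strand(records)
  keep <- cls != "excluded" & !records$unmapped
  n_top <- n_bottom <- integer(length(peaks))
  if (any(keep)) {
    gr <- records_to_granges(records[keep, , drop = FALSE])
    is_top <- cls[keep] == "top"
    hits <- GenomicRanges::findOverlaps(gr, peaks, ignore.strand = TRUE)
    pk <- S4Vectors::subjectHits(hits)
    top_hit <- is_top[S4Vectors::queryHits(hits)]
    n_top <- tabulate(pk[top_hit], nbins = length(peaks))
    n_bottom <- tabulate(pk[!top_hit], nbins = length(peaks))
  }
  tot <- n_top + n_bottom
  s <- ifelse(tot > 0, (n_top - n_bottom) / tot, NA_real_)
  call <- ifelse(tot == 0, "ambiguous", ifelse(s >= 0, "+", "-"))
  call[!is.na(s) & s == 0] <- "ambiguous"
  S4Vectors::mcols(peaks)$n_top <- n_top
  S4Vectors::mcols(peaks)$n_bottom <- n_bottom
  S4Vectors::mcols(peaks)$strandedness <- s
  S4Vectors::mcols(peaks)$rna_strand <- call
  peaks
}

#' Remove the decile of peaks with intermediate strandedness
#'
#' Discards the `floor(fraction * n)` peaks whose scores sit furthest from
#' the +1/-1 endpoints (smallest `|s|`), the quantile reading of removing
#' the 10 % of peaks with intermediate strandedness.  Ties are broken by
#' removing lower read depth first, then by genomic order.
#'
#' @param peaks `GRanges` from [strandedness_score()]; every peak must have
#'   a defined score.
#' @param fraction Fraction to remove, in `[0, 1)`.
#' @return List with elements `retained` and `removed` (both `GRanges`);
#'   their union is the input.
#' @export
filter_intermediate <- function(peaks, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  s <- S4Vectors::mcols(peaks)$strandedness
  if (is.null(s) || anyNA(s))
    stop("all peaks must carry a defined strandedness score")
  n_remove <- floor(fraction * length(peaks))
  depth <- S4Vectors::mcols(peaks)$n_top + S4Vectors::mcols(peaks)$n_bottom
  ord <- order(abs(s), depth,
               as.integer(GenomeInfoDb::seqnames(peaks)),
               BiocGenerics::start(peaks))
  removed_idx <- head(ord, n_remove)
  keep <- rep(TRUE, length(peaks))
  keep[removed_idx] <- FALSE
  list(retained = peaks[keep], removed = peaks[removed_idx])
}

#' Write scored peaks as BED6 plus a full TSV
#'
#' The BED score column carries strandedness scaled to `[-1000, 1000]`.
#'
#' @param peaks Scored peaks (`GRanges`).
#' @param bed_path,tsv_path Output files (either may be `NULL` to skip).
#' @export
write_strandedness <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  mc <- S4Vectors::mcols(peaks)
  if (!is.null(bed_path)) {
    out <- peaks
    S4Vectors::mcols(out)$score <- round(1000 * mc$strandedness)
    str <- mc$rna_strand
    str[str == "ambiguous"] <- "*"
    BiocGenerics::strand(out) <- str
    if (is.null(S4Vectors::mcols(out)$name))
      S4Vectors::mcols(out)$name <- sprintf("peak_%d", seq_along(out))
    write_bed(out, bed_path, bed6 = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                     start = BiocGenerics::start(peaks) - 1,
                     end = BiocGenerics::end(peaks),
                     n_top = mc$n_top, n_bottom = mc$n_bottom,
                     strandedness = mc$strandedness, call = mc$rna_strand)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(peaks)
}
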