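## Strand-oriented metagene profiles.  Bins are fixed-width windows
## anchored at the TSS (or TES) and indexed in transcriptional
## orientation: bin +1 is the first window downstream of the anchor, bin
## -1 the first upstream; minus-strand genes are coordinate-flipped.  A
## peak intersecting a bin increments that bin (presence counting, not
## bp-weighted), in the sense channel when the RNA strand of the hybrid
## equals the gene strand and the antisense channel otherwise.

tss_position <- function(genes) {
  str <- as.character(BiocGenerics::strand(genes))
  if (any(str == "*")) stop("genes must be stranded")
  ifelse(str == "+", BiocGenerics::start(genes), BiocGenerics::end(genes))
}

tes_position <- function(genes) {
  str <- as.character(BiocGenerics::strand(genes))
  if (any(str == "*")) stop("genes must be stranded")
  ifelse(str == "+", BiocGenerics::end(genes), BiocGenerics::start(genes))
}

#' Fixed-width bins around a gene anchor, in transcriptional orientation
#'
#' Bin `+k` covers `[(k-1)*width, k*width)` downstream of the anchor and
#' bin `-k` covers the mirror span upstream; for minus-strand genes the
#' genomic coordinates are flipped accordingly.
#'
#' @param gene A length-1 stranded `GRanges`.
#' @param span_upstream,span_downstream Extent in bp; multiples of `width`.
#' @param width Bin width in bp (default 100).
#' @param anchor `"TSS"` or `"TES"`.
#' @return `GRanges` of bins with an integer `bin` metadata column
#'   (negative upstream, positive downstream; no bin 0).
#' @export
gene_relative_bins <- function(gene, span_upstream = 2000,
                               span_downstream = 5000, width = 100,
                               anchor = c("TSS", "TES")) {
  anchor <- match.arg(anchor)
  if (span_upstream %% width != 0 || span_downstream %% width != 0)
    stop("spans must be multiples of width")
  if (length(gene) != 1) stop("one gene at a time")
  str <- as.character(BiocGenerics::strand(gene))
  if (str == "*") stop("gene must be stranded")
  a <- if (anchor == "TSS") tss_position(gene) else tes_position(gene)
  n_up <- span_upstream / width
  n_dn <- span_downstream / width
  bin <- c(rev(-seq_len(n_up)), seq_len(n_dn))
  ## offsets of each bin's transcription-orientation 5' edge
  off5 <- c(rev(-seq_len(n_up) * width), (seq_len(n_dn) - 1) * width)
  if (str == "+") {
    start <- a + off5
  } else {
    ## `a` (= end(gene), 1-based) is the 0-based half-open TSS boundary;
    ## downstream runs leftward from it
    start <- a - off5 - width + 1
  }
  GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(gene)),
                         IRanges::IRanges(start, width = width),
                         strand = str, bin = bin)
}

all_gene_bins <- function(genes, span_upstream, span_downstream, width,
                          anchor) {
  per <- lapply(seq_along(genes), function(i)
    gene_relative_bins(genes[i], span_upstream, span_downstream, width,
                       anchor))
  bins <- suppressWarnings(do.call(c, per))
  S4Vectors::mcols(bins)$gene <- rep(seq_along(genes),
                                     each = length(per[[1]]))
  bins
}

#' Strand-oriented metagene profile of peak occurrence
#'
#' For every gene and bin, counts the peaks intersecting the bin, split
#' into sense (RNA strand of the hybrid equals the gene strand) and
#' antisense channels, aggregated over genes.
#'
#' @param peaks `GRanges` with `rna_strand` calls (ambiguous peaks are
#'   ignored).
#' @param genes Stranded `GRanges`.
#' @param span_upstream,span_downstream,width,anchor See
#'   [gene_relative_bins()].
#' @return `data.frame` with columns `bin`, `offset` (bp of the bin's 5'
#'   edge relative to the anchor), `sense`, `antisense`, `n_genes`.
#' @export
strand_oriented_profile <- function(peaks, genes, span_upstream = 2000,
                                    span_downstream = 5000, width = 100,
                                    anchor = "TSS") {
  call <- S4Vectors::mcols(peaks)$rna_strand
  if (is.null(call)) stop("peaks carry no rna_strand calls")
  keep <- call %in% c("+", "-")
  peaks <- peaks[keep]; call <- call[keep]
  bins <- all_gene_bins(genes, span_upstream, span_downstream, width,
                        anchor)
  bin_ids <- sort(unique(S4Vectors::mcols(bins)$bin))
  hits <- GenomicRanges::findOverlaps(peaks, bins, ignore.strand = TRUE)
  bh <- S4Vectors::subjectHits(hits)
  gene_strand <- as.character(BiocGenerics::strand(bins))[bh]
  sense <- call[S4Vectors::queryHits(hits)] == gene_strand
  bin_of <- S4Vectors::mcols(bins)$bin[bh]
  idx <- match(bin_of, bin_ids)
  data.frame(
    bin = bin_ids,
    offset = ifelse(bin_ids > 0, (bin_ids - 1) * width, bin_ids * width),
    sense = tabulate(idx[sense], nbins = length(bin_ids)),
    antisense = tabulate(idx[!sense], nbins = length(bin_ids)),
    n_genes = length(genes))
}

#' Expression-stratified metagene profiles
#'
#' Splits genes into a zero-expression class plus `k_quantiles` quantile
#' strata among expressed genes, then computes the strand-oriented profile
#' and the fraction of peak-bearing genes per stratum.
#'
#' @param peaks `GRanges` with `rna_strand` calls.
#' @param genes Stranded `GRanges`; `names(expression)` must cover the
#'   `name` metadata column of `genes`.
#' @param expression Named numeric vector of normalized expression.
#' @param k_quantiles Number of quantile strata among expressed genes
#'   (>= 2).
#' @param peak_region Region used for the peak-bearing gene fraction:
#'   `"gene"` (whole gene body) or `"downstream"` (first
#'   `downstream_bp` after the TSS).
#' @param downstream_bp Extent of the downstream region (default 1500).
#' @param ... Passed to [strand_oriented_profile()].
#' @return List with `profiles` (one `data.frame` per stratum, with a
#'   `stratum` column) and `summary` (`data.frame`: stratum, n_genes,
#'   n_with_peak, fraction_with_peak).
#' @export
expression_strata_profile <- function(peaks, genes, expression,
                                      k_quantiles = 4,
                                      peak_region = c("gene", "downstream"),
                                      downstream_bp = 1500, ...) {
  peak_region <- match.arg(peak_region)
  if (k_quantiles < 2) stop("k_quantiles must be >= 2")
  nm <- S4Vectors::mcols(genes)$name
  if (is.null(nm)) stop("genes need a name metadata column")
  if (!all(nm %in% names(expression)))
    stop("expression table does not cover the gene set")
  expr <- expression[nm]
  stratum <- rep("zero", length(genes))
  pos <- expr > 0
  if (any(pos)) {
    if (sum(pos) < k_quantiles) {
      stratum[pos] <- "Q1"
    } else {
      q <- stats::quantile(expr[pos], probs = seq(0, 1, length.out =
                                                    k_quantiles + 1))
      q[1] <- -Inf; q[length(q)] <- Inf
      stratum[pos] <- paste0("Q", cut(expr[pos], q, labels = FALSE))
    }
  }
  levels <- c("zero", paste0("Q", seq_len(k_quantiles)))
  levels <- levels[levels %in% stratum]
  region <- if (peak_region == "gene") genes else {
    a <- tss_position(genes)
    str <- as.character(BiocGenerics::strand(genes))
    start <- ifelse(str == "+", a, a - downstream_bp + 1)
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(genes)),
                           IRanges::IRanges(pmax(start, 1),
                                            width = downstream_bp),
                           strand = str)
  }
  has_peak <- IRanges::overlapsAny(region, peaks, ignore.strand = TRUE)
  profiles <- list(); summaries <- list()
  for (lv in levels) {
    sel <- stratum == lv
    pr <- strand_oriented_profile(peaks, genes[sel], ...)
    pr$stratum <- lv
    profiles[[lv]] <- pr
    summaries[[lv]] <- data.frame(stratum = lv, n_genes = sum(sel),
                                  n_with_peak = sum(has_peak[sel]),
                                  fraction_with_peak = mean(has_peak[sel]))
  }
  list(profiles = profiles, summary = do.call(rbind, summaries))
}

#' Two-sample test of equal proportions
#'
#' Chi-square test without continuity correction, the standard
#' "proportions test" for contrasts such as peak-bearing transcribed
#' versus non-transcribed genes.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `p1`, `p2`, `difference`, `statistic`, `p_value`.
#' @examples
#' proportions_test(775, 10000, 609, 10000)
#' @export
proportions_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("need 0 <= x <= n in both groups")
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = FALSE))
  list(p1 = x1 / n1, p2 = x2 / n2, difference = x1 / n1 - x2 / n2,
       statistic = unname(ht$statistic), p_value = ht$p.value)
}
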