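## Genomic-context assignment and occupancy enrichment.  Context labels
## are exclusive (a precedence order decides among overlapping features,
## intergenic is the fallback); enrichment against individual feature
## tracks is per-feature, with the observed/expected occupancy ratio and a
## within-chromosome permutation null.

#' Assign each peak an exclusive genomic-context label
#'
#' A peak receives the highest-precedence label among the features it
#' overlaps by at least 1 bp, or `intergenic` when it overlaps none.
#'
#' @param peaks A `GRanges`.
#' @param feature_sets Named list of `GRanges`, one per feature class.
#' @param precedence Character vector, a total order over the labels to
#'   use (highest first).  Every element must name a feature set.
#' @return List with `labels` (character, per peak) and `tally` (named
#'   integer; sums to `length(peaks)`).
#' @export
assign_context <- function(peaks, feature_sets,
                           precedence = names(feature_sets)) {
  unknown <- setdiff(precedence, names(feature_sets))
  if (length(unknown))
    stop("precedence names unknown feature set(s): ",
         paste(unknown, collapse = ", "))
  labels <- rep("intergenic", length(peaks))
  unset <- rep(TRUE, length(peaks))
  for (lab in precedence) {
    if (!any(unset)) break
    hit <- IRanges::overlapsAny(peaks, feature_sets[[lab]],
                                ignore.strand = TRUE)
    labels[unset & hit] <- lab
    unset <- unset & !hit
  }
  tally <- table(factor(labels, levels = c(precedence, "intergenic")))
  list(labels = labels, tally = stats::setNames(as.integer(tally),
                                                names(tally)))
}

#' Observed/expected occupancy enrichment of peaks in a feature
#'
#' Observed is the basepair overlap of the peak union with the feature
#' union; expected is the peak occupancy times the genome fraction the
#' feature covers.
#'
#' @param peaks,feature `GRanges`.
#' @param genome A [Genome].
#' @return List with `observed`, `expected`, `ratio` (all bp except the
#'   dimensionless ratio; `ratio` is `NA` for a zero-occupancy feature).
#' @export
occupancy_enrichment <- function(peaks, feature, genome) {
  obs <- overlap_bp(peaks, feature)
  feat_occ <- union_occupancy(feature)
  expd <- union_occupancy(peaks) * feat_occ / genome_size(genome)
  list(observed = obs, expected = expd,
       ratio = if (expd > 0) obs / expd else NA_real_)
}

#' Permutation test of peak-feature overlap
#'
#' Builds the null distribution of [overlap_bp()] by relocating the peaks
#' uniformly within their chromosomes `n_perm` times
#' ([shuffle_intervals()]) and reports a two-sided empirical p-value with
#' add-one correction, `p = min(1, 2 * (min tail count + 1) / (n_perm + 1))`.
#'
#' @param peaks,feature `GRanges`.
#' @param genome A [Genome].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed; fixed seed gives identical results.
#' @param mask Optional placement mask passed to [shuffle_intervals()].
#' @return List of class `EnrichmentResult`: `observed`, `expected`,
#'   `ratio`, `p_value`, `n_perm`, `null` (the permuted overlaps).
#' @export
permutation_test <- function(peaks, feature, genome, n_perm = 999,
                             seed = NULL, mask = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- overlap_bp(peaks, feature)
  feature <- GenomicRanges::reduce(feature, ignore.strand = TRUE)
  null <- if (is.null(mask)) {
    ## exact but fast: same uniform within-chromosome relocation as
    ## shuffle_intervals, union overlap via prefix sums on linearized
    ## coordinates
    with_seed(seed, fast_null_overlaps(peaks, feature, genome, n_perm))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i)
      overlap_bp(shuffle_intervals(peaks, genome, mask = mask), feature),
      0))
  }
  hi <- sum(null >= obs)
  lo <- sum(null <= obs)
  p <- min(1, 2 * (min(hi, lo) + 1) / (n_perm + 1))
  enr <- occupancy_enrichment(peaks, feature, genome)
  structure(list(observed = obs, expected = enr$expected,
                 ratio = enr$ratio, p_value = p, n_perm = n_perm,
                 null = null),
            class = "EnrichmentResult")
}

## Null overlap distribution without GRanges overhead: chromosomes are
## embedded in one linear axis (with spacers wider than any interval so
## nothing merges across them); feature overlap of an interval is a
## difference of prefix sums; shuffled peaks are merged before summing so
## the statistic is exactly overlap_bp of the union.
fast_null_overlaps <- function(peaks, feature, genome, n_perm) {
  validate_intervals(peaks, genome)
  w <- BiocGenerics::width(peaks)
  chr <- as.character(GenomeInfoDb::seqnames(peaks))
  if (any(w > genome$seqlengths[chr]))
    stop("interval longer than its chromosome")
  spacer <- max(w, 1) + 1
  lens <- genome$seqlengths
  off <- stats::setNames(c(0, cumsum(lens + spacer))[seq_along(lens)],
                         names(lens))
  fs <- off[as.character(GenomeInfoDb::seqnames(feature))] +
    BiocGenerics::start(feature)
  fe <- off[as.character(GenomeInfoDb::seqnames(feature))] +
    BiocGenerics::end(feature)
  o <- order(fs)
  fs <- fs[o]; fe <- fe[o]
  cum <- cumsum(fe - fs + 1)
  covered <- function(pos) {        # feature bp in (-Inf, pos]
    idx <- findInterval(pos, fs)
    out <- numeric(length(pos))
    nz <- idx > 0
    out[nz] <- cum[idx[nz]] - pmax(0, fe[idx[nz]] - pos[nz])
    out
  }
  max_start <- lens[chr] - w + 1
  base <- off[chr]
  n <- length(peaks)
  vapply(seq_len(n_perm), function(i) {
    st <- base + floor(runif(n) * max_start) + 1
    en <- st + w - 1
    o <- order(st)
    st <- st[o]; en <- en[o]
    ## merge overlapping shuffled intervals
    ce <- cummax(en)
    new <- c(TRUE, st[-1] > ce[-n] + 0)
    grp <- cumsum(new)
    ms <- st[new]
    me <- as.numeric(tapply(en, grp, max))
    sum(covered(me) - covered(ms - 1))
  }, 0)
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "observed %.0f bp / expected %.1f bp (ratio %.3f), permutation p = %.4g (n_perm = %d)\n",
    x$observed, x$expected, x$ratio, x$p_value, x$n_perm))
  invisible(x)
}

#' Enrichment table across several feature tracks
#'
#' Runs [permutation_test()] per feature set and collects a tidy table.
#'
#' @param peaks `GRanges`.
#' @param feature_sets Named list of `GRanges`.
#' @param genome A [Genome].
#' @param n_perm Permutations per feature.
#' @param seed Optional seed; per-feature seeds are derived from it.
#' @return `data.frame` with feature, observed, expected, ratio, p_value,
#'   n_perm.
#' @export
enrichment_table <- function(peaks, feature_sets, genome, n_perm = 999,
                             seed = NULL) {
  rows <- lapply(seq_along(feature_sets), function(i) {
    r <- permutation_test(peaks, feature_sets[[i]], genome, n_perm,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(feature = names(feature_sets)[i], observed = r$observed,
               expected = r$expected, ratio = r$ratio,
               p_value = r$p_value, n_perm = r$n_perm)
  })
  do.call(rbind, rows)
}

#' Subfamily breakdown of repeat-overlapping peaks
#'
#' For each repeat family, the fraction of family-overlapping peaks that
#' also overlap each subfamily (a peak may touch several subfamilies;
#' denominators are reported).
#'
#' @param peaks `GRanges`.
#' @param repeats `GRanges` with `family` and `subfamily` metadata columns.
#' @return `data.frame` with family, subfamily, n (peaks hitting the
#'   subfamily), n_family (peaks hitting the family), fraction.
#' @export
repeat_family_breakdown <- function(peaks, repeats) {
  fam <- S4Vectors::mcols(repeats)$family
  sub <- S4Vectors::mcols(repeats)$subfamily
  if (is.null(fam) || is.null(sub))
    stop("repeats need family and subfamily metadata columns")
  out <- list()
  for (f in unique(fam)) {
    rf <- repeats[fam == f]
    in_family <- IRanges::overlapsAny(peaks, rf, ignore.strand = TRUE)
    nf <- sum(in_family)
    if (nf == 0) next
    for (s in unique(S4Vectors::mcols(rf)$subfamily)) {
      ns <- sum(IRanges::overlapsAny(
        peaks[in_family], rf[S4Vectors::mcols(rf)$subfamily == s],
        ignore.strand = TRUE))
      out[[length(out) + 1]] <- data.frame(
        family = f, subfamily = s, n = ns, n_family = nf,
        fraction = ns / nf)
    }
  }
  if (!length(out))
    return(data.frame(family = character(), subfamily = character(),
                      n = integer(), n_family = integer(),
                      fraction = numeric()))
  do.call(rbind, out)
}

#' Fraction of peaks overlapping a feature
#'
#' Returns the proportion of peaks with >= 1 bp overlap, plus the logical
#' overlap indicator so proportions can be chained (`peaks[res$overlaps]`
#' against a second track).
#'
#' @param peaks,feature `GRanges`.
#' @return List with `n`, `k`, `proportion`, `overlaps`.
#' @export
overlap_proportion <- function(peaks, feature) {
  if (!length(peaks))
    return(list(n = 0L, k = 0L, proportion = NA_real_,
                overlaps = logical()))
  ov <- IRanges::overlapsAny(peaks, feature, ignore.strand = TRUE)
  list(n = length(peaks), k = sum(ov), proportion = mean(ov),
       overlaps = ov)
}

#' Methylation contrast inside peaks versus genome-wide
#'
#' Unweighted per-CpG means of a methylation track (values in `[0, 1]`)
#' inside the peak union versus over all sites, their difference, and a
#' two-sided Wilcoxon rank-sum comparison.
#'
#' @param peaks `GRanges`.
#' @param methylation `GRanges` with per-CpG `score` in `[0, 1]` (e.g.
#'   from [read_bedgraph()]).
#' @return List with `mean_in_peaks`, `mean_genome`, `difference`,
#'   `p_value`, `n_in_peaks`, `n_total`.
#' @export
methylation_contrast <- function(peaks, methylation) {
  v <- S4Vectors::mcols(methylation)$score
  if (is.null(v)) stop("methylation track needs a score column")
  inside <- IRanges::overlapsAny(methylation, peaks, ignore.strand = TRUE)
  if (!any(inside))
    return(list(mean_in_peaks = NA_real_, mean_genome = mean(v),
                difference = NA_real_, p_value = NA_real_,
                n_in_peaks = 0L, n_total = length(v)))
  m_in <- mean(v[inside]); m_all <- mean(v)
  p <- if (any(!inside))
    suppressWarnings(stats::wilcox.test(v[inside], v[!inside])$p.value)
  else NA_real_
  list(mean_in_peaks = m_in, mean_genome = m_all,
       difference = m_in - m_all, p_value = p,
       n_in_peaks = sum(inside), n_total = length(v))
}
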