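## Seeded generator of synthetic directional RDIP-seq experiments.
##
## The generator plants the signal structure the downstream analysis is
## designed to detect: peaks whose RNA-derived strand is purine-enriched
## (per-base purine probability 0.5 + delta on the planted strand),
## directional read pairs whose second-in-pair read reports the planted
## strand with probability p_strand (flags 163/147), peak placement
## multiplied inside promoters, extra peaks immediately downstream of the
## TSS of highly expressed genes, a methylation decrement inside peaks,
## and 500-kb-window peak densities driven by planted covariates.  All
## distributional choices are stand-ins (the real experiment's generative
## process is unknown); the planted truth is returned alongside each
## output so parameter recovery is testable.

#' Simulation configuration
#'
#' Defaults describe a desk-scale experiment: 2 chromosomes x 5 Mb,
#' 200 genes, 500 peaks, ~50 read pairs per peak, `p_strand = 0.95`,
#' purine-skew effect `delta = 0.15`, 5x promoter placement enrichment,
#' and a 40-window x 12-covariate density regression with planted
#' coefficients (3, 2, 1, 0, ...).
#'
#' @param seed Integer master seed; all outputs are byte-identical for a
#'   fixed seed.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_genes,gene_length_meanlog,gene_length_sdlog Gene count and
#'   log-normal length distribution.
#' @param promoter_width Total promoter width, centered on the TSS (bp).
#' @param n_peaks,peak_length_mean,peak_length_sd Peak count and normal
#'   length distribution (truncated at 200 bp).
#' @param reads_per_peak Mean of the Poisson read-pair count per peak.
#' @param read_length,insert_size Read and fragment geometry (bp).
#' @param p_strand Probability a read pair reports the planted RNA strand.
#' @param delta Planted excess purine fraction on the RNA strand (so its
#'   expected purine fraction is `0.5 + delta`).
#' @param promoter_enrichment Peak placement multiplier inside promoters.
#' @param tss_peak_fraction Fraction of peaks planted in the first
#'   `tss_window` bp downstream of TSSs, genes sampled proportionally to
#'   expression.
#' @param tss_window Extent of the downstream-of-TSS planting region (bp).
#' @param zero_inflation Fraction of genes with zero expression.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param n_cpg,meth_mean,meth_decrement,meth_concentration Methylation
#'   track: site count, Beta mean outside/decrement inside peaks,
#'   concentration.
#' @param n_windows,n_covariates,covariate_rho,coefficients,noise_sd
#'   Window-density regression: size, AR(1) covariate correlation,
#'   planted coefficients (recycled/truncated to `n_covariates`), and
#'   Gaussian noise SD.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 200,
                       gene_length_meanlog = log(20000),
                       gene_length_sdlog = 0.5,
                       promoter_width = 2000,
                       n_peaks = 500,
                       peak_length_mean = 600,
                       peak_length_sd = 150,
                       reads_per_peak = 50,
                       read_length = 100,
                       insert_size = 300,
                       p_strand = 0.95,
                       delta = 0.15,
                       promoter_enrichment = 5,
                       tss_peak_fraction = 0.25,
                       tss_window = 1500,
                       zero_inflation = 0.3,
                       expr_meanlog = 2,
                       expr_sdlog = 1,
                       n_cpg = 20000,
                       meth_mean = 0.7,
                       meth_decrement = 0.1,
                       meth_concentration = 20,
                       n_windows = 40,
                       n_covariates = 12,
                       covariate_rho = 0.3,
                       coefficients = c(3, 2, 1),
                       noise_sd = 0.5) {
  cfg <- as.list(environment())
  stopifnot(p_strand >= 0.5, p_strand <= 1, delta >= 0, delta <= 0.5,
            promoter_enrichment >= 1, all(chrom_lengths > 0),
            zero_inflation >= 0, zero_inflation < 1,
            abs(covariate_rho) < 1, n_covariates >= 2)
  beta <- rep(0, n_covariates)
  beta[seq_len(min(length(coefficients), n_covariates))] <-
    coefficients[seq_len(min(length(coefficients), n_covariates))]
  cfg$coefficients <- beta
  structure(cfg, class = "SimulationConfig")
}

## sample `length(widths)` non-overlapping intervals uniformly inside a
## territory (GRanges); returns GRanges.  Rejection on overlap with
## previously placed intervals in `avoid`.
place_intervals <- function(widths, territory, avoid = NULL,
                            max_rounds = 100) {
  territory <- GenomicRanges::reduce(territory, ignore.strand = TRUE)
  tchr <- as.character(GenomeInfoDb::seqnames(territory))
  tstart <- BiocGenerics::start(territory)
  twidth <- BiocGenerics::width(territory)
  n <- length(widths)
  res_chr <- character(n); res_start <- numeric(n)
  taken <- if (is.null(avoid)) GenomicRanges::GRanges()
           else GenomicRanges::reduce(GenomicRanges::granges(avoid),
                                      ignore.strand = TRUE)
  unplaced <- order(widths, decreasing = TRUE)   # big ones claim room first
  for (round in seq_len(max_rounds)) {
    if (!length(unplaced)) break
    w <- widths[unplaced]
    segs <- integer(length(w)); sts <- numeric(length(w))
    for (i in seq_along(w)) {
      room <- twidth - w[i] + 1
      ok <- room > 0
      if (!any(ok))
        stop("no territory segment can hold width ", w[i])
      k <- sample.int(sum(ok), 1, prob = room[ok])
      seg <- which(ok)[k]
      segs[i] <- seg
      sts[i] <- tstart[seg] + floor(runif(1) * room[seg])
    }
    cand <- GenomicRanges::GRanges(tchr[segs],
                                   IRanges::IRanges(sts, width = w))
    bad <- IRanges::overlapsAny(cand, taken)
    ## within-batch conflicts: drop any candidate overlapping a
    ## lower-indexed one (the survivor keeps its draw)
    hits <- GenomicRanges::findOverlaps(cand, cand)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    bad[unique(sh[qh < sh])] <- TRUE
    if (any(!bad)) {
      idx <- unplaced[!bad]
      res_chr[idx] <- tchr[segs[!bad]]
      res_start[idx] <- sts[!bad]
      taken <- GenomicRanges::reduce(suppressWarnings(
        c(taken, GenomicRanges::granges(cand[!bad]))))
      unplaced <- unplaced[bad]
    }
  }
  if (length(unplaced))
    stop("could not place interval of width ", widths[unplaced[1]],
         " without overlap")
  GenomicRanges::GRanges(res_chr, IRanges::IRanges(res_start,
                                                   width = widths))
}

random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, n,
                                                    replace = TRUE)]))
}

#' Simulate a genome with annotation tracks
#'
#' Background sequence is uniform over A/C/G/T.  Gene, promoter
#' (TSS +/- `promoter_width/2`), CpG-island, repeat-family, DNase, and
#' histone-domain tracks are returned as `GRanges`; genes carry strand
#' and names.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [Genome] with sequence) and `features`
#'   (named list of `GRanges`: genes, promoters, cpg_islands, repeats,
#'   dnase, H3K27me3, H3K9me3).
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    seqs <- Biostrings::DNAStringSet(vapply(config$chrom_lengths,
                                            random_dna, ""))
    names(seqs) <- names(config$chrom_lengths)
    genome <- Genome(config$chrom_lengths, seqs)
    whole <- GenomicRanges::GRanges(names(config$chrom_lengths),
                                    IRanges::IRanges(1, config$chrom_lengths))
    if (config$n_genes > 0) {
      glen <- pmin(pmax(round(rlnorm(config$n_genes,
                                     config$gene_length_meanlog,
                                     config$gene_length_sdlog)), 2000),
                   min(config$chrom_lengths) %/% 4)
      genes <- place_intervals(glen, whole)
      BiocGenerics::strand(genes) <- sample(c("+", "-"),
                                            length(genes), TRUE)
      S4Vectors::mcols(genes)$name <- sprintf("gene%03d",
                                              seq_along(genes))
      tss <- tss_position(genes)
      half <- config$promoter_width %/% 2
      prom <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(genes)),
        IRanges::IRanges(pmax(tss - half, 1),
                         pmin(tss + half - 1,
                              config$chrom_lengths[
                                as.character(GenomeInfoDb::seqnames(genes))])))
      S4Vectors::mcols(prom)$name <- S4Vectors::mcols(genes)$name
      has_cgi <- runif(length(genes)) < 0.6
      cgi_prom <- GenomicRanges::resize(prom[has_cgi], width = 800,
                                        fix = "center")
      cgi_rand <- place_intervals(rep(800, max(round(30 * genome_size(genome) / 1e7), 1)), whole)
      cpg <- suppressWarnings(c(GenomicRanges::granges(cgi_prom), cgi_rand))
    } else {
      genes <- GenomicRanges::GRanges()
      S4Vectors::mcols(genes)$name <- character()
      prom <- GenomicRanges::GRanges()
      cpg <- place_intervals(rep(800, max(round(30 * genome_size(genome) / 1e7), 1)), whole)
    }
    ## annotation densities scaled to genome size (references: per 10 Mb)
    sf <- genome_size(genome) / 1e7
    n_sat <- max(round(40 * sf), 2)
    n_l1 <- max(round(120 * sf), 2)
    n_lc <- max(round(80 * sf), 2)
    fam <- c(rep("Satellite", n_sat), rep("L1", n_l1),
             rep("Low_complexity", n_lc))
    subfam <- c(sample(c("(GAATG)n", "other_sat"), n_sat, TRUE,
                       prob = c(0.765, 0.235)),
                sample(c("L1PA2", "L1_other"), n_l1, TRUE),
                sample(c("GA-rich", "other_lc"), n_lc, TRUE))
    rep_w <- round(runif(length(fam), 300, 4000))
    repeats <- place_intervals(rep_w, whole)
    S4Vectors::mcols(repeats)$family <- fam
    S4Vectors::mcols(repeats)$subfamily <- subfam
    dnase <- place_intervals(rep(300, max(round(400 * sf), 2)), whole)
    dom_w <- function(k) round(runif(k, 1e5, 4e5) * min(sf, 1))
    k27 <- place_intervals(pmax(dom_w(max(round(8 * sf), 1)), 1e4), whole)
    k9 <- place_intervals(pmax(dom_w(max(round(6 * sf), 1)), 1e4), whole)
    list(genome = genome,
         features = list(genes = genes, promoters = prom,
                         cpg_islands = cpg, repeats = repeats,
                         dnase = dnase, H3K27me3 = k27, H3K9me3 = k9))
  })
}

#' Simulate gene expression
#'
#' Zero-inflated log-normal expression, named by gene.
#'
#' @param config A [sim_config()].
#' @param genes `GRanges` with a `name` column.
#' @return Named numeric vector.
#' @export
simulate_expression <- function(config, genes) {
  with_seed(config$seed + 101L, {
    n <- length(genes)
    expr <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    expr[runif(n) < config$zero_inflation] <- 0
    stats::setNames(expr, S4Vectors::mcols(genes)$name)
  })
}

#' Simulate peaks, planted skew, and directional read pairs
#'
#' Peak placement probability is multiplied by `promoter_enrichment`
#' inside promoters; a `tss_peak_fraction` share of peaks is planted in
#' the first `tss_window` bp downstream of TSSs of expression-weighted
#' genes (when `expression` is supplied).  The genome sequence inside
#' each peak is rewritten so the planted RNA strand has per-base purine
#' probability `0.5 + delta`.  Read pairs are emitted as aligned SAM
#' records: the second-in-pair, RNA-derived read gets flag 163 when it
#' reports the top strand and 147 for the bottom strand, matching the
#' planted strand with probability `p_strand`.
#'
#' @param config A [sim_config()].
#' @param genome A [Genome] with sequence (from [simulate_genome()]).
#' @param features Feature list from [simulate_genome()].
#' @param expression Optional named expression vector (see
#'   [simulate_expression()]).
#' @return List with `peaks` (`GRanges`), `records` (SAM record data
#'   frame, both mates), `genome` (sequence rewritten inside peaks), and
#'   `truth` (`data.frame`: peak, planted_strand, purine_prob, n_pairs).
#' @export
simulate_peaks_and_reads <- function(config, genome, features,
                                     expression = NULL) {
  with_seed(config$seed + 202L, {
    n <- config$n_peaks
    widths <- pmax(round(rnorm(n, config$peak_length_mean,
                               config$peak_length_sd)), 200)
    whole <- GenomicRanges::GRanges(names(genome$seqlengths),
                                    IRanges::IRanges(1, genome$seqlengths))
    prom <- GenomicRanges::reduce(features$promoters,
                                  ignore.strand = TRUE)
    f <- union_occupancy(prom) / genome_size(genome)
    m <- config$promoter_enrichment
    q <- m * f / (m * f + (1 - f))
    n_tss <- if (!is.null(expression) && length(features$genes))
      round(config$tss_peak_fraction * n) else 0
    genes <- features$genes
    parts <- list()
    if (n_tss > 0) {
      ## expression-weighted genes get peaks in the first tss_window bp
      ## downstream of their TSS (floor keeps silent genes possible)
      wts <- expression[S4Vectors::mcols(genes)$name]
      wts <- wts + 0.05 * mean(wts[wts > 0])
      pick <- sample.int(length(genes), n_tss, replace = TRUE, prob = wts)
      tssp <- tss_position(genes)
      str <- as.character(BiocGenerics::strand(genes))[pick]
      gchr <- as.character(GenomeInfoDb::seqnames(genes))[pick]
      w <- widths[seq_len(n_tss)]
      ws <- ifelse(str == "+", tssp[pick], tssp[pick] - config$tss_window + 1)
      we <- ws + config$tss_window - 1
      lo <- pmax(ws - w + 1, 1)
      hi <- pmin(we, genome$seqlengths[gchr] - w + 1)
      st <- lo + floor(runif(n_tss) * pmax(hi - lo + 1, 1))
      parts$tss <- GenomicRanges::GRanges(gchr,
                                          IRanges::IRanges(st, width = w))
    }
    nonprom <- GenomicRanges::setdiff(whole, prom, ignore.strand = TRUE)
    in_prom <- length(prom) > 0 & runif(n - n_tss) < q
    w_rest <- widths[seq(n_tss + 1, length.out = n - n_tss)]
    if (any(in_prom))
      parts$prom <- place_intervals(w_rest[in_prom], prom,
                                    avoid = parts$tss)
    if (any(!in_prom))
      parts$bg <- place_intervals(w_rest[!in_prom], nonprom,
                                  avoid = suppressWarnings(
                                    do.call(c, unname(parts))))
    peaks <- suppressWarnings(do.call(c, unname(parts)))
    ## TSS-planted peaks were drawn independently: relocate any overlaps
    hits <- GenomicRanges::findOverlaps(peaks, peaks)
    clash <- unique(S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)])
    if (length(clash)) {
      repl <- place_intervals(BiocGenerics::width(peaks)[clash], whole,
                              avoid = peaks[-clash])
      peaks <- suppressWarnings(c(peaks[-clash], repl))
    }
    peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
    S4Vectors::mcols(peaks)$name <- sprintf("peak_%04d", seq_along(peaks))
    ## plant purine skew on the RNA strand and rewrite the genome
    planted <- sample(c("+", "-"), length(peaks), TRUE)
    seqs <- genome$sequence
    new_seq <- Biostrings::DNAStringSet(vapply(
      seq_along(peaks), function(i) {
        w <- BiocGenerics::width(peaks)[i]
        purine <- runif(w) < 0.5 + config$delta
        paste(ifelse(purine, sample(c("A", "G"), w, TRUE),
                     sample(c("C", "T"), w, TRUE)), collapse = "")
      }, ""))
    flip <- planted == "-"
    new_seq[flip] <- Biostrings::reverseComplement(new_seq[flip])
    pk_chr <- as.character(GenomeInfoDb::seqnames(peaks))
    for (chr in unique(pk_chr)) {
      sel <- pk_chr == chr
      seqs[[chr]] <- Biostrings::replaceAt(
        seqs[[chr]],
        IRanges::IRanges(BiocGenerics::start(peaks)[sel],
                         BiocGenerics::end(peaks)[sel]),
        new_seq[sel])
    }
    genome <- Genome(genome$seqlengths, seqs)
    ## directional read pairs (vectorized across all peaks)
    n_pairs <- rpois(length(peaks), config$reads_per_peak)
    L <- config$read_length
    ins <- config$insert_size
    flags <- rna_evidence_flags()
    pk <- rep(seq_along(peaks), n_pairs)
    npr <- length(pk)
    chr <- pk_chr[pk]
    clen <- genome$seqlengths[chr]
    s <- BiocGenerics::start(peaks)[pk]
    e <- BiocGenerics::end(peaks)[pk]
    report_planted <- runif(npr) < config$p_strand
    other <- c("+" = "-", "-" = "+")
    rep_strand <- ifelse(report_planted, planted[pk],
                         other[planted[pk]])
    ## R2 (the RNA-derived read) must overlap its peak by >= 1 bp
    pos2 <- pmin(pmax(floor(runif(npr) * (e - s + L)) + s - L + 1, 1),
                 clen - L + 1)
    top <- rep_strand == "+"
    ## R2 forward: mate reverse, fragment extends right; reversed else
    pos1 <- pmin(pmax(ifelse(top, pos2 + ins - L, pos2 + L - ins), 1),
                 clen - L + 1)
    qn <- sprintf("%s_r%04d", S4Vectors::mcols(peaks)$name[pk],
                  unlist(lapply(n_pairs, seq_len)))
    seq_of <- function(p) as.character(Biostrings::subseq(
      seqs[chr], start = p, width = L))
    flag1 <- ifelse(top,
                    sam_flag(paired = TRUE, proper_pair = TRUE,
                             reverse = TRUE, first_in_pair = TRUE),
                    sam_flag(paired = TRUE, proper_pair = TRUE,
                             mate_reverse = TRUE, first_in_pair = TRUE))
    records <- data.frame(
      qname = c(qn, qn),
      flag = c(ifelse(top, flags[["top"]], flags[["bottom"]]), flag1),
      chrom = c(chr, chr),
      pos = c(pos2, pos1),
      mapq = 60L,
      cigar = sprintf("%dM", L),
      rnext = "=",
      pnext = c(pos1, pos2),
      tlen = c(ifelse(top, pos1 + L - pos2, -(pos2 + L - pos1)),
               ifelse(top, -(pos1 + L - pos2), pos2 + L - pos1)),
      seq = c(seq_of(pos2), seq_of(pos1)))
    records$qual <- strrep("I", L)
    records$read_len <- L
    records$unmapped <- FALSE
    records$proper_pair <- TRUE
    ## interleave mates: R2 then R1 per pair
    records <- records[as.vector(rbind(seq_len(npr), npr + seq_len(npr))), ]
    rownames(records) <- NULL
    truth <- data.frame(peak = S4Vectors::mcols(peaks)$name,
                        chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                        start = BiocGenerics::start(peaks) - 1,
                        end = BiocGenerics::end(peaks),
                        planted_strand = planted,
                        purine_prob = 0.5 + config$delta,
                        n_pairs = n_pairs)
    list(peaks = peaks, records = records, genome = genome,
         truth = truth)
  })
}

#' Simulate expression-linked tracks
#'
#' Methylation is Beta-distributed per CpG site with mean
#' `meth_mean - meth_decrement` inside peaks and `meth_mean` elsewhere;
#' transcribed intervals cover the expressed gene bodies plus a set of
#' random intergenic loci.
#'
#' @param config A [sim_config()].
#' @param genes `GRanges` with names.
#' @param peaks Optional peak `GRanges` (for the methylation decrement).
#' @param expression Optional expression vector; generated when absent.
#' @return List with `expression`, `methylation` (`GRanges` with
#'   `score`), `transcribed` (`GRanges`).
#' @export
simulate_expression_and_tracks <- function(config, genes, peaks = NULL,
                                           expression = NULL) {
  if (is.null(expression)) expression <- simulate_expression(config, genes)
  with_seed(config$seed + 303L, {
    chrlen <- config$chrom_lengths
    chr <- sample(names(chrlen), config$n_cpg, TRUE,
                  prob = chrlen / sum(chrlen))
    pos <- floor(runif(config$n_cpg) * chrlen[chr]) + 1
    cpg <- GenomicRanges::sort(GenomicRanges::GRanges(
      chr, IRanges::IRanges(pos, width = 1)))
    mu <- rep(config$meth_mean, length(cpg))
    if (!is.null(peaks))
      mu[IRanges::overlapsAny(cpg, peaks, ignore.strand = TRUE)] <-
        config$meth_mean - config$meth_decrement
    cc <- config$meth_concentration
    S4Vectors::mcols(cpg)$score <- rbeta(length(cpg), mu * cc,
                                         (1 - mu) * cc)
    expressed <- GenomicRanges::reduce(
      genes[expression[S4Vectors::mcols(genes)$name] > 0],
      ignore.strand = TRUE)
    whole <- GenomicRanges::GRanges(names(chrlen),
                                    IRanges::IRanges(1, chrlen))
    intergenic_tx <- place_intervals(
      rep(2000, max(round(60 * sum(chrlen) / 1e7), 1)), whole, avoid = genes)
    transcribed <- GenomicRanges::reduce(
      suppressWarnings(c(expressed, intergenic_tx)))
    list(expression = expression, methylation = cpg,
         transcribed = transcribed)
  })
}

#' Simulate window covariates and peak-density response
#'
#' Covariates are multivariate normal with AR(1) correlation
#' `covariate_rho`; the response is their linear combination under the
#' planted coefficients plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param n_windows Number of windows (defaults to `config$n_windows`;
#'   may also be a `GRanges` of windows, in which case its length is
#'   used).
#' @return List with `covariates` (n x p matrix), `response`, `truth`
#'   (`coefficients`, `active`, `noise_sd`).
#' @export
simulate_window_density <- function(config, n_windows = NULL) {
  if (methods::is(n_windows, "GRanges")) n_windows <- length(n_windows)
  if (is.null(n_windows)) n_windows <- config$n_windows
  p <- config$n_covariates
  rho <- config$covariate_rho
  Sigma <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("singular covariate correlation"))
  with_seed(config$seed + 404L, {
    Z <- matrix(rnorm(n_windows * p), n_windows, p)
    X <- Z %*% R
    colnames(X) <- sprintf("cov%02d", seq_len(p))
    beta <- config$coefficients
    y <- drop(X %*% beta) + rnorm(n_windows, 0, config$noise_sd)
    list(covariates = X, response = y,
         truth = list(coefficients = beta, active = which(beta != 0),
                      noise_sd = config$noise_sd))
  })
}

#' Run the full synthetic experiment
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome` (post-rewrite), `features`,
#'   `expression`, `peaks`, `records`, `truth`, `tracks`, and
#'   `window_density`.
#' @export
simulate_rdip <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  expr <- simulate_expression(config, gen$features$genes)
  pk <- simulate_peaks_and_reads(config, gen$genome, gen$features,
                                 expression = expr)
  tracks <- simulate_expression_and_tracks(config, gen$features$genes,
                                           peaks = pk$peaks,
                                           expression = expr)
  wd <- simulate_window_density(config)
  list(config = config, genome = pk$genome, features = gen$features,
       expression = expr, peaks = pk$peaks, records = pk$records,
       truth = pk$truth, tracks = tracks, window_density = wd)
}

#' Write simulated records as SAM text
#'
#' @param records Record data frame from [simulate_peaks_and_reads()].
#' @param genome A [Genome] (for the `@SQ` header lines).
#' @param path Output file.
#' @export
write_sam <- function(records, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seqlengths),
                   as.integer(genome$seqlengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, records$flag, records$chrom,
                  as.integer(records$pos), records$mapq, records$cigar,
                  records$rnext, as.integer(records$pnext),
                  as.integer(records$tlen), records$seq, records$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an expression table as TSV
#' @param expression Named numeric vector.
#' @param path Output file.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(data.frame(gene = names(expression),
                                expression = unname(expression)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
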