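## Shared fixtures and independent oracles.  Simulations are memoized so
## expensive generators run once per test session.

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

## compact GRanges constructor from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand, ...)
}

small_config <- function(seed = 42) {
  sim_config(seed = seed,
             chrom_lengths = c(chrA = 4e5, chrB = 3e5),
             n_genes = 24, gene_length_meanlog = log(6000),
             gene_length_sdlog = 0.4,
             n_peaks = 60, reads_per_peak = 30,
             n_cpg = 4000)
}

small_sim <- function() memo("small_sim", simulate_rdip(small_config()))

default_sim <- function() memo("default_sim", simulate_rdip(sim_config(seed = 2024)))

small_scored <- function() memo("small_scored", {
  sim <- small_sim()
  strandedness_score(sim$peaks, sim$records)
})

## brute-force composition oracle: plain character counting
oracle_counts <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(b) sum(ch == b), 0L)
}

oracle_skew <- function(s) {
  k <- oracle_counts(s)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(at = rat(k[["A"]] - k[["T"]], k[["A"]] + k[["T"]]),
       gc = rat(k[["G"]] - k[["C"]], k[["G"]] + k[["C"]]),
       pur = rat(k[["G"]] + k[["A"]],
                 k[["A"]] + k[["C"]] + k[["G"]] + k[["T"]]))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## coordinate-descent lasso oracle: minimizes
## 0.5 ||y - X b||^2 + lambda ||b||_1 by cyclic soft-thresholding
cd_lasso <- function(X, y, lambda, tol = 1e-13, max_iter = 100000) {
  p <- ncol(X)
  b <- rep(0, p)
  G <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  gj <- diag(G)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      r <- Xty[j] - sum(G[j, ] * b) + gj[j] * b[j]
      bj <- sign(r) * max(abs(r) - lambda, 0) / gj[j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

## SAM record row in the shape read_sam_records() returns
sam_rec <- function(flag, chrom, pos, len = 100, qname = "q") {
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = pos, mapq = 60L, cigar = sprintf("%dM", len),
             rnext = "=", pnext = pos, tlen = len,
             seq = strrep("A", len), qual = strrep("I", len),
             read_len = len, unmapped = bitwAnd(as.integer(flag), 4L) > 0,
             proper_pair = bitwAnd(as.integer(flag), 2L) > 0)
}
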