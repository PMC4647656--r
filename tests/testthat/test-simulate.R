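test_that("a fixed seed reproduces every output byte-identically", {
  cfg <- small_config()
  a <- small_sim()
  b <- simulate_rdip(cfg)
  expect_identical(as.character(a$genome$sequence),
                   as.character(b$genome$sequence))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression, b$expression)
  expect_identical(a$window_density$covariates,
                   b$window_density$covariates)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_sam(a$records, a$genome, f1)
  write_sam(b$records, b$genome, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("background base composition is near-uniform", {
  cfg <- sim_config(seed = 6, chrom_lengths = c(c1 = 2e6), n_genes = 0,
                    n_peaks = 0)
  g <- simulate_genome(cfg)
  fr <- Biostrings::letterFrequency(g$genome$sequence[[1]],
                                    c("A", "C", "G", "T"), as.prob = TRUE)
  expect_true(all(abs(fr - 0.25) < 0.01))
  expect_length(g$features$genes, 0)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(p_strand = 0.4))
  expect_error(sim_config(delta = 0.6))
  expect_error(sim_config(promoter_enrichment = 0.5))
  expect_error(sim_config(covariate_rho = 1))
})

test_that("features stay within chromosome bounds", {
  sim <- small_sim()
  g <- Genome(small_config()$chrom_lengths)
  for (f in sim$features)
    expect_silent(validate_intervals(f, g))
  expect_silent(validate_intervals(sim$peaks, g))
})

test_that("p_strand = 1 makes every pair report the planted strand", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(c1 = 3e5), n_genes = 10,
                    gene_length_meanlog = log(4000), n_peaks = 25,
                    p_strand = 1, tss_peak_fraction = 0)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks_and_reads(cfg, gen$genome, gen$features)
  r2 <- pk$records[pk$records$flag %in% c(163L, 147L), ]
  ## map each R2 to its peak via the qname prefix
  peak_of <- sub("_r\\d+$", "", r2$qname)
  planted <- stats::setNames(pk$truth$planted_strand, pk$truth$peak)
  expect_true(all(ifelse(r2$flag == 163L, "+", "-") ==
                    planted[peak_of]))
})

test_that("delta = 0 leaves the RNA strand unskewed", {
  cfg <- sim_config(seed = 10, chrom_lengths = c(c1 = 4e5), n_genes = 10,
                    gene_length_meanlog = log(4000), n_peaks = 40,
                    delta = 0)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks_and_reads(cfg, gen$genome, gen$features)
  sc <- strandedness_score(pk$peaks, pk$records)
  sk <- rna_strand_skew(sc, pk$genome)
  se <- sd(sk$purine_fraction) / sqrt(nrow(sk))
  expect_lt(abs(mean(sk$purine_fraction) - 0.5), 3 * se)
})

test_that("promoter placement follows the enrichment mixture", {
  ## 100 genes x 1 kb promoters on 1 Mb = 10% occupancy, multiplier 5:
  ## expected in-promoter fraction 5*0.1/(5*0.1+0.9) ~= 0.357
  cfg <- sim_config(seed = 12, chrom_lengths = c(c1 = 1e6),
                    n_genes = 100, gene_length_meanlog = log(4000),
                    gene_length_sdlog = 0.2, promoter_width = 1000,
                    n_peaks = 400, peak_length_mean = 300,
                    peak_length_sd = 30, promoter_enrichment = 5,
                    tss_peak_fraction = 0, reads_per_peak = 1)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks_and_reads(cfg, gen$genome, gen$features)
  prom <- gen$features$promoters
  f <- union_occupancy(prom) / 1e6
  expected <- 5 * f / (5 * f + 1 - f)
  observed <- overlap_proportion(pk$peaks, prom)$proportion
  expect_lt(abs(observed - expected),
            3 * sqrt(expected * (1 - expected) / 400) + 0.02)
})

test_that("expression is zero-inflated as configured", {
  sim <- small_sim()
  ## binomial noise at n = 24 genes: 3 SE band around 0.3
  expect_lt(abs(mean(sim$expression == 0) - 0.3),
            3 * sqrt(0.3 * 0.7 / length(sim$expression)))
  expect_true(all(sim$expression >= 0))
})

test_that("emitted SAM records are internally consistent mates", {
  sim <- small_sim()
  r <- sim$records
  expect_true(all(r$flag %in% c(163L, 147L, 83L, 99L)))
  r2 <- r[r$flag %in% c(163L, 147L), ]
  r1 <- r[r$flag %in% c(83L, 99L), ]
  expect_equal(nrow(r2), nrow(r1))
  m <- match(r2$qname, r1$qname)
  expect_false(anyNA(m))
  expect_equal(r2$pnext, r1$pos[m])
  expect_equal(r1$pnext[m], r2$pos)
  ## mate strand bits agree: 163 pairs with 83, 147 with 99
  expect_true(all(ifelse(r2$flag == 163L, 83L, 99L) == r1$flag[m]))
  expect_equal(r2$tlen, -r1$tlen[m])
  ## and the SAM file parses back to the same facts
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(r, sim$genome, f)
  back <- read_sam_records(f)
  expect_equal(back$flag, r$flag)
  expect_equal(back$pos, r$pos)
  expect_equal(back$seq, r$seq)
})

test_that("window-density truth is recoverable and seeded", {
  cfg <- sim_config(seed = 15)
  a <- simulate_window_density(cfg)
  b <- simulate_window_density(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_equal(a$truth$active, 1:3)
  ## null config: response is pure noise at the configured sd
  null_cfg <- sim_config(seed = 16, coefficients = 0, n_windows = 2000,
                         noise_sd = 0.5)
  z <- simulate_window_density(null_cfg)
  expect_equal(sd(z$response), 0.5, tolerance = 0.05)
  expect_equal(cor(z$covariates[, 1], z$covariates[, 2]), 0.3,
               tolerance = 0.1)
  ## a single dominant covariate enters the path first
  one <- simulate_window_density(sim_config(seed = 17,
                                            coefficients = c(0, 0, 5),
                                            n_windows = 100))
  d <- standardize_design(one$covariates, one$response)
  expect_equal(lars_lasso_path(d)$entries$variable[1], 3)
})

test_that("transcribed intervals cover expressed genes", {
  sim <- small_sim()
  genes <- sim$features$genes
  expressed <- genes[sim$expression[S4Vectors::mcols(genes)$name] > 0]
  expect_true(all(IRanges::overlapsAny(expressed,
                                       sim$tracks$transcribed,
                                       type = "within")))
})
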