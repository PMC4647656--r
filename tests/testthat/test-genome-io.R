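test_that("read_bed maps the 3-6 column dialect to GRanges", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk\t0\t+",
               "chr1\t300\t400",
               "chr2\t0\t50\tx\t7\t-"), f)
  gr <- read_bed(f)
  expect_equal(BiocGenerics::start(gr), c(101, 301, 1))
  expect_equal(BiocGenerics::end(gr), c(200, 400, 50))
  expect_equal(as.character(BiocGenerics::strand(gr)), c("+", "*", "-"))
  expect_equal(S4Vectors::mcols(gr)$name[1], "pk")
})

test_that("read_bed rejects malformed lines with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t100"), f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("BED text round-trips through write_bed/read_bed", {
  set.seed(11)
  for (rep in 1:5) {
    gr <- gr0(sample(c("chr1", "chr2"), 20, TRUE),
              st <- sample(1e5, 20), st + sample(5000, 20),
              strand = sample(c("+", "-", "*"), 20, TRUE),
              name = sprintf("iv%02d", 1:20))
    f <- withr::local_tempfile(fileext = ".bed")
    write_bed(gr, f)
    back <- read_bed(f)
    expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr))
    expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr))
    expect_equal(as.character(BiocGenerics::strand(back)),
                 as.character(BiocGenerics::strand(gr)))
  }
})

test_that("read_sam_records parses mandatory fields and flag bits", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:10000",
               "r1\t163\tchr1\t500\t60\t100M\t=\t700\t300\tAAAA\tIIII",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tCCCC\tIIII"), f)
  rec <- read_sam_records(f)
  expect_equal(rec$flag, c(163L, 4L))
  expect_equal(rec$pos[1], 500)
  expect_equal(rec$read_len[1], 100)   # reference span from CIGAR
  expect_false(rec$unmapped[1])
  expect_true(rec$unmapped[2])
  expect_true(rec$proper_pair[1])
})

test_that("read_sam_records handles empty bodies and malformed lines", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6"), f)
  expect_equal(nrow(read_sam_records(f)), 0)
  writeLines(c("@HD\tVN:1.6", "r1\t163\tchr1\t500"), f)
  expect_error(read_sam_records(f), "line 2")
})

test_that("union_occupancy counts overlapping basepairs once", {
  expect_equal(union_occupancy(gr0("c", c(0, 5), c(10, 15))), 15)
  expect_equal(union_occupancy(gr0("c", 0, 10)), 10)
  expect_equal(union_occupancy(GenomicRanges::GRanges()), 0)
  g <- Genome(c(c1 = 100))
  expect_error(union_occupancy(gr0("c1", 90, 120), g), "beyond")
})

test_that("overlap_bp is the occupancy of the intersection", {
  a <- gr0("c", 0, 10); b <- gr0("c", 5, 15)
  expect_equal(overlap_bp(a, b), 5)
  expect_equal(overlap_bp(b, a), 5)
  expect_equal(overlap_bp(gr0("c", 0, 10), gr0("c", 20, 30)), 0)
  expect_equal(overlap_bp(a, a), union_occupancy(a))
  expect_error(overlap_bp(gr0("c1", 0, 10), gr0("c2", 0, 10)),
               "namespace")
})

test_that("inclusion-exclusion holds on random interval sets", {
  set.seed(7)
  for (rep in 1:20) {
    a <- gr0("c", sa <- sample(1000, 15), sa + sample(100, 15))
    b <- gr0("c", sb <- sample(1000, 15), sb + sample(100, 15))
    expect_equal(overlap_bp(a, b),
                 union_occupancy(a) + union_occupancy(b) -
                   union_occupancy(c(a, b)))
  }
})

test_that("make_windows tiles chromosomes and keeps the partial tail", {
  g <- Genome(c(c1 = 1e6))
  expect_length(make_windows(g, 5e5), 2)
  g2 <- Genome(c(c1 = 120))
  w <- make_windows(g2, 50)
  expect_equal(BiocGenerics::start(w), c(1, 51, 101))
  expect_equal(BiocGenerics::end(w), c(50, 100, 120))
  expect_equal(S4Vectors::mcols(w)$partial, c(FALSE, FALSE, TRUE))
  w1 <- make_windows(g2, 500)
  expect_length(w1, 1)
  expect_true(S4Vectors::mcols(w1)$partial)
  expect_error(make_windows(g, 0), "positive")
})

test_that("shuffle_intervals is seeded, length-preserving, and uniform", {
  g <- Genome(c(c1 = 1e5, c2 = 5e4))
  gr <- gr0(rep(c("c1", "c2"), c(6, 4)), s <- sample(1e4, 10),
            s + sample(500, 10))
  a <- shuffle_intervals(gr, g, seed = 3)
  b <- shuffle_intervals(gr, g, seed = 3)
  expect_identical(BiocGenerics::start(a), BiocGenerics::start(b))
  expect_equal(sort(BiocGenerics::width(a)),
               sort(BiocGenerics::width(gr)))
  expect_equal(table(as.character(GenomeInfoDb::seqnames(a))),
               table(as.character(GenomeInfoDb::seqnames(gr))))
  expect_error(shuffle_intervals(gr0("c2", 0, 9e4), g),
               "beyond|longer")
  ## uniform starts: one batched call draws iid uniforms per interval
  many <- gr0(rep("c1", 1e5), rep(0, 1e5), rep(100, 1e5))
  st <- BiocGenerics::start(shuffle_intervals(many, g, seed = 8))
  dec <- cut(st, breaks = seq(1, 1e5 - 99, length.out = 11),
             include.lowest = TRUE)
  expect_gt(suppressWarnings(stats::chisq.test(table(dec))$p.value), 0.01)
})

test_that("mask restricts shuffle placement", {
  g <- Genome(c(c1 = 1e5))
  mask <- gr0("c1", c(1000, 50000), c(2000, 60000))
  gr <- gr0("c1", rep(0, 50), rep(300, 50))
  sh <- shuffle_intervals(gr, g, seed = 4, mask = mask)
  expect_true(all(IRanges::overlapsAny(sh, mask, type = "within")))
})

test_that("sam_flag composes bits in SAM order", {
  expect_equal(sam_flag(paired = TRUE, unmapped = TRUE), 5L)
  expect_equal(sam_flag(paired = TRUE, proper_pair = TRUE,
                        reverse = TRUE, first_in_pair = TRUE), 83L)
  expect_equal(sam_flag(paired = TRUE, proper_pair = TRUE,
                        mate_reverse = TRUE, first_in_pair = TRUE), 99L)
})

test_that("FASTA round-trips through a Genome", {
  g <- Genome(c(cA = 50, cB = 30),
              Biostrings::DNAStringSet(c(cA = random_seq(50),
                                         cB = random_seq(30))))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  back <- read_genome_fasta(f)
  expect_equal(back$seqlengths, g$seqlengths)
  expect_equal(as.character(back$sequence), as.character(g$sequence))
})
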