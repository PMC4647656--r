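#' @import methods
#' @importFrom stats rbinom rnorm runif rpois rlnorm rbeta quantile sd
#'   coef lm resid pexp ks.test binom.test wilcox.test prop.test ecdf rexp
#' @importFrom utils head tail write.table read.table
NULL

## Interval convention: on disk, BED-style 0-based half-open; in memory,
## GRanges (1-based closed) as everywhere in Bioconductor.  All conversions
## happen in read_bed()/write_bed() and nowhere else.

#' Genome object
#'
#' A light container for a reference genome: chromosome names and lengths,
#' plus (optionally) the sequence itself as a [Biostrings::DNAStringSet].
#'
#' @param seqlengths Named integer/numeric vector of chromosome lengths (bp).
#' @param sequence Optional `DNAStringSet` with one entry per chromosome;
#'   widths must equal `seqlengths`.
#' @return An object of class `Genome` with elements `seqlengths` and
#'   `sequence`.
#' @examples
#' g <- Genome(c(chr1 = 1000, chr2 = 500))
#' @export
Genome <- function(seqlengths, sequence = NULL) {
  if (is.null(names(seqlengths)) || anyNA(names(seqlengths)))
    stop("seqlengths must be a named vector")
  seqlengths <- stats::setNames(as.numeric(seqlengths), names(seqlengths))
  if (any(seqlengths <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet"))
      sequence <- Biostrings::DNAStringSet(sequence)
    if (!setequal(names(sequence), names(seqlengths)))
      stop("sequence names do not match seqlengths names")
    sequence <- sequence[names(seqlengths)]
    if (!all(Biostrings::width(sequence) == seqlengths))
      stop("sequence widths disagree with declared lengths")
  }
  structure(list(seqlengths = seqlengths, sequence = sequence),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome: %d chromosome(s), %.3g bp total, sequence %s\n",
              length(x$seqlengths), sum(x$seqlengths),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Total genome size in basepairs
#' @param genome A [Genome].
#' @export
genome_size <- function(genome) sum(genome$seqlengths)

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A [Genome] with sequence.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Genome(stats::setNames(Biostrings::width(seqs), names(seqs)), seqs)
}

#' Write a genome to FASTA
#' @param genome A [Genome] carrying sequence.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  Biostrings::writeXStringSet(genome$sequence, path)
  invisible(path)
}

seqinfo_of <- function(genome) {
  GenomeInfoDb::Seqinfo(names(genome$seqlengths),
                        as.integer(genome$seqlengths))
}

#' Check intervals against a genome
#'
#' Errors when an interval runs off its chromosome end or names an unknown
#' chromosome.
#' @param gr A `GRanges`.
#' @param genome A [Genome].
#' @export
validate_intervals <- function(gr, genome) {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(chr), names(genome$seqlengths))
  if (length(unknown))
    stop("intervals on chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  len <- genome$seqlengths[chr]
  if (any(BiocGenerics::end(gr) > len) || any(BiocGenerics::start(gr) < 1))
    stop("interval extends beyond chromosome bounds")
  invisible(gr)
}

#' Read a BED file into a GRanges
#'
#' Accepts the 3- to 6-column BED dialect.  BED coordinates (0-based,
#' half-open) are converted to the 1-based closed convention of `GRanges`;
#' the strand column is honoured when present, otherwise intervals are
#' unstranded (`*`).
#'
#' @param path BED file.
#' @param genome Optional [Genome]; when given, intervals are validated
#'   against it and the `GRanges` carries its seqinfo.
#' @return A `GRanges`, with a `name` metadata column when the file has one.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- seqinfo_of(genome)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("invalid interval at BED line ", lineno[bad[1]],
         ": need 0 <= start < end")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], "*"), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (any(nf >= 4)) S4Vectors::mcols(gr)$name <- name
  if (any(nf >= 5)) {
    score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5L]] else NA_character_, "")))
    S4Vectors::mcols(gr)$score <- score
  }
  if (!is.null(genome)) {
    validate_intervals(gr, genome)
    GenomeInfoDb::seqlevels(gr) <- names(genome$seqlengths)
    GenomeInfoDb::seqinfo(gr) <- seqinfo_of(genome)
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when `name`/`score`/strand information is present, BED3
#' otherwise.  Coordinates are converted back to 0-based half-open, so
#' `read_bed(write_bed(gr))` is the identity on coordinates.
#'
#' @param gr A `GRanges`.
#' @param path Output file.
#' @param bed6 Force BED6 output.
#' @export
write_bed <- function(gr, path, bed6 = NULL) {
  mc <- S4Vectors::mcols(gr)
  has_extra <- !is.null(mc$name) || !is.null(mc$score) ||
    any(as.character(BiocGenerics::strand(gr)) != "*")
  if (is.null(bed6)) bed6 <- has_extra
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = BiocGenerics::end(gr))
  if (bed6) {
    df$name <- if (!is.null(mc$name)) mc$name else "."
    df$score <- if (!is.null(mc$score)) mc$score else 0
    str <- as.character(BiocGenerics::strand(gr))
    str[str == "*"] <- "."
    df$strand <- str
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return A `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "score"))
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1, dt$end),
                         score = dt$score)
}

#' Write a bedGraph track
#' @param gr `GRanges` with a numeric `score` column.
#' @param path Output file.
#' @export
write_bedgraph <- function(gr, path) {
  df <- data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
                   S4Vectors::mcols(gr)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## reference-consumed span of a CIGAR string (M/D/N/=/X)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(toks)) return(0)
    op <- substring(toks, nchar(toks))
    n <- as.numeric(substring(toks, 1, nchar(toks) - 1))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0, USE.NAMES = FALSE)
}

#' Read alignment records from a SAM text file
#'
#' Parses the eleven mandatory SAM columns into a data frame of the
#' alignment facts the strandedness analysis needs.  Binary BAM is out of
#' scope; convert upstream with `samtools view -h`.
#'
#' @param path SAM file (with or without header lines).
#' @return A `data.frame` with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `read_len` (reference span),
#'   `seq`, and logical `unmapped` and `proper_pair` decoded from the flag.
#' @export
read_sam_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  cols <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
            "rnext", "pnext", "tlen", "seq", "qual")
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), 11), cols))
    df$flag <- integer(); df$pos <- numeric()
    df$read_len <- numeric(); df$unmapped <- logical(); df$proper_pair <- logical()
    return(df)
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM line ", body[which(nf < 11)[1]],
         ": fewer than 11 mandatory columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  df <- data.frame(qname = get(1), flag = as.integer(get(2)),
                   chrom = get(3), pos = as.numeric(get(4)),
                   mapq = as.integer(get(5)), cigar = get(6),
                   rnext = get(7), pnext = as.numeric(get(8)),
                   tlen = as.numeric(get(9)), seq = get(10))
  df$read_len <- ifelse(df$cigar == "*", nchar(df$seq),
                        cigar_ref_span(df$cigar))
  df$unmapped <- bitwAnd(df$flag, 4L) > 0L
  df$proper_pair <- bitwAnd(df$flag, 2L) > 0L
  df
}

#' Compose a SAM bit flag
#'
#' Builds the integer flag from the named template bits of the SAM
#' specification.  Used to state, rather than hard-code, the flag values of
#' the directional library model: the RNA-derived second-in-pair read of a
#' proper pair gets 163 when it aligns to the top (forward) strand and 147
#' when it aligns to the bottom (reverse) strand.
#'
#' @param paired,proper_pair,unmapped,mate_unmapped,reverse,mate_reverse,
#'   first_in_pair,second_in_pair,secondary,qc_fail,duplicate,supplementary
#'   Logical template bits (0x1 ... 0x800 in SAM order).
#' @return Integer flag.
#' @examples
#' sam_flag(paired = TRUE, proper_pair = TRUE, mate_reverse = TRUE,
#'          second_in_pair = TRUE)  # 163
#' @export
sam_flag <- function(paired = FALSE, proper_pair = FALSE, unmapped = FALSE,
                     mate_unmapped = FALSE, reverse = FALSE,
                     mate_reverse = FALSE, first_in_pair = FALSE,
                     second_in_pair = FALSE, secondary = FALSE,
                     qc_fail = FALSE, duplicate = FALSE,
                     supplementary = FALSE) {
  bits <- c(paired, proper_pair, unmapped, mate_unmapped, reverse,
            mate_reverse, first_in_pair, second_in_pair, secondary,
            qc_fail, duplicate, supplementary)
  as.integer(sum(as.integer(bits) * 2^(0:11)))
}

#' Basepairs covered by the union of intervals
#'
#' Overlapping intervals are counted once ("nucleotide occupancy").
#'
#' @param gr A `GRanges`.
#' @param genome Optional [Genome] for bounds validation.
#' @return Numeric basepair count.
#' @export
union_occupancy <- function(gr, genome = NULL) {
  if (!is.null(genome)) validate_intervals(gr, genome)
  sum(as.numeric(BiocGenerics::width(
    GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

#' Basepairs shared by two interval sets
#'
#' Occupancy of the intersection of the two unions; symmetric in its
#' arguments.
#'
#' @param a,b `GRanges` on the same chromosome namespace.
#' @return Numeric basepair count.
#' @export
overlap_bp <- function(a, b) {
  if (length(a) && length(b)) {
    na <- unique(as.character(GenomeInfoDb::seqnames(a)))
    nb <- unique(as.character(GenomeInfoDb::seqnames(b)))
    if (!length(intersect(na, nb)) &&
        !length(intersect(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))))
      stop("interval sets share no chromosome namespace")
  }
  ra <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  rb <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  suppressWarnings(
    sum(as.numeric(BiocGenerics::width(
      GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)))))
}

#' Tile a genome into non-overlapping windows
#'
#' Windows start at the chromosome origin; the terminal window keeps its
#' true (possibly partial) width and is flagged, so per-bp normalization
#' stays honest.
#'
#' @param genome A [Genome].
#' @param width Window width in bp (> 0).
#' @return A `GRanges` with a logical `partial` metadata column.
#' @export
make_windows <- function(genome, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a single positive number")
  starts <- lapply(genome$seqlengths, function(len) seq(1, len, by = width))
  chrom <- rep(names(genome$seqlengths), lengths(starts))
  st <- unlist(starts, use.names = FALSE)
  en <- pmin(st + width - 1, genome$seqlengths[chrom])
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en),
                                partial = en - st + 1 < width)
  GenomeInfoDb::seqinfo(win) <- seqinfo_of(genome)
  win
}

## run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly relocate intervals within their chromosomes
#'
#' The permutation null for enrichment testing: each interval keeps its
#' length and chromosome but receives a uniformly random start among the
#' valid positions.  Overlaps among shuffled intervals are permitted.  An
#' optional mask restricts placement to starts whose interval lies wholly
#' inside the mask (e.g. to exclude assembly gaps).
#'
#' @param gr A `GRanges`.
#' @param genome A [Genome].
#' @param seed Optional integer; fixed seed gives identical output.
#' @param mask Optional `GRanges` of allowed territory.
#' @return A `GRanges` of the same length, lengths preserved per interval.
#' @export
shuffle_intervals <- function(gr, genome, seed = NULL, mask = NULL) {
  validate_intervals(gr, genome)
  w <- BiocGenerics::width(gr)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  if (any(w > genome$seqlengths[chr]))
    stop("interval longer than its chromosome")
  with_seed(seed, {
    if (is.null(mask)) {
      max_start <- genome$seqlengths[chr] - w + 1
      new_start <- floor(runif(length(gr)) * max_start) + 1
    } else {
      mask <- GenomicRanges::reduce(mask, ignore.strand = TRUE)
      new_start <- numeric(length(gr))
      mchr <- as.character(GenomeInfoDb::seqnames(mask))
      for (i in seq_along(gr)) {
        seg <- mask[mchr == chr[i]]
        room <- BiocGenerics::width(seg) - w[i] + 1
        seg <- seg[room > 0]; room <- room[room > 0]
        if (!length(seg))
          stop("mask leaves no room for an interval of width ", w[i],
               " on ", chr[i])
        k <- sample.int(length(seg), 1, prob = room)
        new_start[i] <- BiocGenerics::start(seg)[k] +
          floor(runif(1) * room[k])
      }
    }
    out <- GenomicRanges::GRanges(chr, IRanges::IRanges(new_start, width = w),
                                  strand = BiocGenerics::strand(gr))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    GenomeInfoDb::seqinfo(out) <- seqinfo_of(genome)
    out
  })
}
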