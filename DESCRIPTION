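Package: rdipr
Title: Downstream Analysis of Directional RNA:DNA Hybrid Sequencing
Version: 0.1.0
Authors@R: person("RDIP", "Tools", email = "rdipr@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of directional RDIP-seq
    (RNA:DNA hybrid immunoprecipitation sequencing) experiments.
    Infers the RNA-derived strand of each read pair from SAM flags,
    scores per-peak strandedness and applies a decile noise filter,
    computes nucleotide skew statistics (AT/GC skew, purine fraction)
    on the called RNA strand, tests genomic-context enrichment of peaks
    with a permutation null, builds strand-oriented metagene profiles
    stratified by expression, normalizes ribosomal DNA coverage against
    input, and fits LASSO-path regressions of regional peak density via
    least-angle regression with the covariance test for each entering
    covariate. A seeded synthetic-data generator emulates the signal
    structure of a directional hybrid-mapping experiment so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
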