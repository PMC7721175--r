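Package: svintegrate
Title: Integrative Filtering of Structural Variants from Short-Read and Linked-Read Sequencing
Version: 0.1.0
Authors@R: person("SV", "Integrate Developers", email = "svintegrate@example.org", role = c("aut", "cre"))
Description: Cross-technology merging and comparison of structural-variant (SV)
    calls from conventional short-read and 10x-style linked-read whole-genome
    sequencing, breakpoint-fusion template construction and requantification of
    junction reads and spanning pairs, linked-read barcode (GEM) support
    counting, breakpoint annotation with repeat and mappability tracks and
    local coverage, per-technology logistic-regression filters with a combined
    union model, benchmarking against PCR-style truth tables, and a synthetic
    linked-read/short-read data generator so that the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
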