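Package: svmap
Title: Assembly-to-Assembly Structural Variant Discovery, Comparative
    Scaffolding and Long-Read Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers structural variants (copy-number gains and losses,
    transposable-element and other insertions and deletions, inversions,
    SNPs and small indels) by whole-genome alignment of two assemblies:
    maximal exact matches are chained into collinear clusters, filled to
    base-level alignments, filtered to one-to-one synteny blocks, and
    alignment disagreements are classified into typed variant calls with
    copy-number verification of duplication candidates.  Also provides a
    reference-guided comparative scaffolder, long-read spanning-read
    validation of variant calls, a seeded genome/variant/read simulator
    with exact truth records, and small downstream statistics (Fisher
    meta-analysis of rank-sum tests, temperature-gradient interpolation,
    paralog-specific FPKM, and duplicate-allele frequency estimation from
    divergent read pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
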