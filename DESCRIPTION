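Package: clipem
Title: CLIP-Seq Peak Calling with an Enrichment Mixture Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding protein binding sites from CLIP-seq data
    by comparing an immunoprecipitation (foreground) library against a
    size-matched input or RNA-seq background. Genomic windows are scored with
    a two-component mixture model (log-normal multiplicative noise convolved
    with Poisson sampling noise for unbound windows, a uniform enrichment
    component for bound ones) fitted by expectation-maximization; enriched
    regions are deconvolved into individual binding peaks with a Gaussian
    mixture; binding sites are extracted around coverage-peak centers or
    modal read-start (crosslink) positions; and known sequence motifs are
    scored by posterior-based enrichment against weakly enriched background
    sequences. A CLIP experiment simulator models crosslinking, RNase
    protection and reverse-transcriptase truncation, explaining when
    crosslink positions localize binding motifs better than coverage peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
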