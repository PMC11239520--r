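Package: retroepi
Title: Locus-Resolved Retrotransposon Methylation and Promoter Activity from
    Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for LINE-1 (L1) retrotransposon regulatory
    activity in sorted neuron populations. Aggregates nanopolish-style per-CpG
    methylation calls over genome bins and full-length element 5'UTRs, calls
    per-locus differential methylation between cell populations with Fisher's
    exact test and Bonferroni correction, classifies transcription start sites
    from 5'RACE long reads, detects chimeric L1-promoter to gene transcripts
    with reading-frame verification, scores targeted bisulfite monomer
    amplicons, and generates fully synthetic inputs with known ground truth
    for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
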