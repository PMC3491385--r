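Package: medipromo
Title: Promoter DNA Methylation Analysis for MeDIP Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed one-sided Kolmogorov-Smirnov enrichment scoring of
    MeDIP-chip tiling-array probes, run-based methylation peak calling with
    replicate-consistent promoter methylation and hypomethylation calls,
    CpG-island-style classification of promoters into high- and low-CpG
    classes, TSS-anchored metagene profiles, and contingency statistics
    linking promoter methylation state to histone marks and developmental
    expression cohorts. Includes a fully seeded synthetic-data generator
    that emulates tiled MeDIP experiments with planted methylated and
    hypomethylated domains so that every stage of the pipeline can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
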