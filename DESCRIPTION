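Package: sweepscan
Title: Selection-Signature Scans from Phased Haplotype Data
Version: 0.1.0
Authors@R: person("sweepscan", "developers", role = c("aut", "cre"),
    email = "sweepscan@example.org")
Description: A windowed genome-scan toolkit for detecting signatures of
    positive selection in phased diploid resequencing data. Implements
    pooled heterozygosity (Hp/ZHp), the integrated haplotype score (iHS),
    cross-population extended haplotype homozygosity (XP-EHH), and windowed
    Weir-Cockerham FST on a shared sliding-window grid, with empirical
    extreme-percentile outlier calling, bedtools-style interval
    consolidation, and gene-overlap annotation. Ships a forward-in-time
    Wright-Fisher island-model simulator with an optional hard selective
    sweep so the whole pipeline is testable end to end without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
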