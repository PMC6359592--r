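Package: threeCquant
Title: 3C-qPCR Interaction Profiling and Chromatin Loop Calling with
    Companion qPCR, ddPCR and ChIP-qPCR Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of chromosome conformation capture (3C)
    experiments read out by TaqMan qPCR: in silico restriction digestion of a
    locus into a fragment map with TSS-relative coordinates, control-locus
    normalized interaction-frequency profiles, a power-law distance-decay
    background with iterative peak exclusion, and fold-enrichment based
    chromatin loop calling. Ships the companion bench quantifications that
    typically accompany a 3C study: delta-delta-Ct relative expression with
    reference genes, restriction-digestion efficiency QC, ChIP-qPCR percent
    input and fold enrichment over IgG, and droplet digital PCR Poisson
    concentration estimates. A seeded synthetic-data generator emulates a
    ~200-kb locus and every plate type the pipeline consumes, so the full
    analysis is testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
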