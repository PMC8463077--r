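Package: peakmotifs
Title: Motif Classes of Co-Occupied Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-factor ChIP-seq peak sets built
    around co-activators (YAP/TAZ) that reach DNA through sequence-specific
    partners (TEAD, AP-1, STAT3). Provides summit-centered peak processing
    (signal smoothing, summit calling, fixed-width summit windows,
    TSS-proximity annotation), position-weight-matrix scanning with exact
    p-value score thresholds, per-peak motif-class assignment,
    accessibility-matched control sampling from a DHS atlas, chi-square
    motif and co-occurrence enrichment, paralog-specific site calling from
    replicate counts with knockout confirmation, crosslinking-ratio versus
    motif-score correlation, and motif-class gene-signature survival
    stratification (gene signature scores, Kaplan-Meier, log-rank). A
    seeded synthetic-data generator with recorded ground truth exercises
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    DESeq2
Config/testthat/edition: 3
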