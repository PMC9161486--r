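Package: isomiR5p
Title: 5'isomiR Quantification, Shifted-Seed Target Prediction and
    Gene-Set Activity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for 5'isomiRs, microRNA variants whose 5'
    end (and therefore seed) is shifted relative to the canonical mature
    miRNA. Classifies small-RNA reads into 5'isomiRs of an annotated
    precursor while aggregating over 3'-end heterogeneity, normalizes to
    reads per million, performs tumor-versus-normal differential
    expression with Benjamini-Hochberg control and volcano
    classification, predicts shifted-seed targets over expressed 3'UTRs
    by intersecting a canonical seed-match scanner with a
    complementarity duplex score, computes a single-sample gene-set
    activity score (median of z-scaled expression), runs a
    self-contained preranked and phenotype-permutation GSEA with the
    weighted Kolmogorov-Smirnov statistic, and provides proteome
    two-group statistics including downshifted-Gaussian imputation of
    left-censored intensities. Ships simulators for every input so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
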