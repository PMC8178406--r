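Package: cardioregion
Title: Chamber-Enrichment Analysis of Cardiac RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for regional transcriptomics of the four-chambered
    heart: percentile-anchored FPKM normalization, negative-binomial pairwise
    differential expression with covariate adjustment, an eight-class
    subregion-enrichment classifier with a rank-based heart-enrichment rule,
    Fisher's exact gene-set over-representation, and reference-based cell-type
    deconvolution by weighted non-negative least squares with multi-reference
    ensembling. Includes seeded synthetic-data generators with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
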