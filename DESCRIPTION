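Package: gliomastate
Title: Glioblastoma Cell-State Scoring, Enrichment and Functional-Assay
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying therapy- and vessel-induced cell-state
    plasticity in glioblastoma. Implements bin-matched control-gene
    meta-module scoring of single cells, four-state (NPC/OPC/AC/MES)
    classification with a two-dimensional "butterfly" state projection,
    derivation and intersection of therapy-induced gene signatures,
    pre-ranked permutation gene-set enrichment (ES/NES/FDR) with paired
    up/down/no-change calls, spatially weighted correlation of signature
    surfaces on spatial-transcriptomics grids, kinase-activity z-scores
    from site-level phosphoproteomic fold changes, and closed-form
    quantification of dye-dilution division numbers, vascular
    association, vessel co-option and reporter-based reprogramming
    assays. A seeded synthetic-data generator with recorded ground truth
    emulates the statistical structure of each input so every step is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
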