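Package: stemFEA
Title: Signature Scoring, AUC Enrichment and Stemness Analysis for Single-Cell and Cohort Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize quiescent stem-like cell
    populations in single-cell RNA-seq data and to relate their gene
    signatures to patient outcome. Implements per-cell z-scored gene
    signature scoring with ROC-AUC cluster-enrichment calls (AUC > 0.6
    with Wilcoxon rank-sum P < 0.01), derivation of cluster signatures
    from differentially expressed genes, cell-cycle phase scoring and
    regression, per-cell pathway-activity classification, bulk-cohort
    signature stratification with survival and association tests,
    single-hit Poisson limiting-dilution (ELDA-style) frequency
    estimation, and a negative-binomial count simulator with planted
    programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    jsonlite
biocViews: SingleCell, Transcriptomics, GeneSetEnrichment, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
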