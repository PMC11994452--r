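Package: afcellsig
Title: Cell-Type Resolution of Atrial Fibrillation Expression Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns atrial-fibrillation (AF) differential expression to
    cardiac cell types by integrating bulk RNA-seq cohorts with paired
    single-nucleus RNA/ATAC (multiome) data. Provides pseudobulk
    negative-binomial differential expression with cross-cohort concordance
    and a strandedness-artifact check, one-vs-rest Wilcoxon AUC specificity
    scoring, construction and binned-control scoring of a
    cardiomyocyte-specific AF gene signature, KNN meta-cell aggregation,
    chromVAR-style motif deviation z-scores with bias-matched background
    peaks, Tn5 footprint profiles, driver transcription-factor selection by
    dual motif/expression correlation, open-chromatin peak annotation
    against cCRE and enhancer-atlas interval sets, and signed weighted
    coexpression modules (topological overlap). A synthetic multiome and
    bulk-cohort generator with planted ground truth makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    mclust,
    jsonlite
Config/testthat/edition: 3
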