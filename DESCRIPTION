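Package: procrustes
Title: Cross-Platform Batch Effect Correction for RNA-Seq via Per-Gene
    Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transforms exome-capture (EC) RNA-seq expression profiles into
    poly-A-like profiles with per-gene regression models: a single-gene
    model (sProcrustes) and a multi-gene model (mProcrustes) that adds
    co-expressed genes as predictors via cross-validated elastic net.
    Includes the surrounding workflow: gene filtering by probe effective
    length, co-expression feature selection, baseline batch correctors
    (z-score, batch mean centering, per-gene coefficient scaling),
    concordance evaluation (Lin's concordance correlation coefficient,
    RMSE, signed-rank tests, ANOVA power), projection of single samples
    onto a reference poly-A cohort through truncated SVD and nearest
    centroids, and a synthetic paired-cohort simulator with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
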