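Package: stimmod
Title: Module Structure of Stimulation-Response Mass-Cytometry Immune Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-donor immune features from stimulation-response
    mass-cytometry event tables (arcsinh-transformed per-cell-type signaling
    medians, baseline-subtracted and responsiveness-thresholded), detects
    modules of correlated features by hierarchical clustering plus adjacency
    thresholding, computes per-donor module scores, compares sex-stratified
    correlation structure and score distributions (Wilcoxon rank-sum,
    Kolmogorov-Smirnov, Benjamini-Hochberg), performs SAM-style permutation
    differential-feature analysis, and fits ridge, lasso, group-lasso and
    sparse-group-lasso logistic classifiers via proximal gradient descent.
    Includes a synthetic cohort generator with planted signaling-protein
    modules and configurable sex effects so the whole pipeline is testable
    without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
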