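Package: sparsewrap
Title: Sparse Wrapper Model Sets for Binary Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sparse wrapper feature selection for binary classification of
    expression cohorts: a screening step over all one-feature logistic models
    followed by dimension-growing steps with repeated stratified k-fold
    cross-validation and alpha-quantile retention, yielding a set of small,
    near-equivalent predictive models rather than a single one. Includes
    single-versus-associative coefficient analysis to detect antagonistic
    features (Yule-Simpson sign reversals), model-set co-occurrence networks
    with bootstrap Spearman correlation inference, ROC regions, a lasso
    baseline, a synthetic cohort generator with planted effects and correlated
    blocks, and a reproducible end-to-end pipeline with TSV/JSON/GraphML
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
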