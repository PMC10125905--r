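Package: nestfold
Title: Nested Cross-Validation with Embedded Feature Selection and Class
    Balancing for High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully nested k x l-fold cross-validation for classifiers and
    regression models in the P >> n regime typical of transcriptomics.
    Univariate and model-based feature filters, class rebalancing
    (random over/undersampling, SMOTE) and hyperparameter tuning are all
    embedded strictly inside outer training folds so that pooled
    out-of-fold predictions give unbiased performance estimates. Includes
    an elastic-net tuner that cross-validates both the mixing parameter
    alpha and the penalty lambda on inner folds, an outer-CV-only mode for
    tuning-free learners, and a simulation harness demonstrating the
    optimism bias of non-nested feature filtering on pure-noise data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    parallel,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
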