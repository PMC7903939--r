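Package: deconfound
Title: Leakage-Aware Confound Regression Pipelines for Predictive Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for removing confounding signal (e.g. brain size in
    sex decoding from resting-state fMRI features) from feature tables before
    predictive modelling. Implements per-feature linear confound regression as
    a fit/apply operator, composed with z-score normalization into whole-data
    (WDCR) and cross-validated (CVCR) removal schemes; ridge and partial least
    squares decoders with inner-CV hyperparameter tuning; repeated stratified
    k-fold evaluation with AUC, F1 and balanced accuracy; residual-confounding
    diagnostics (univariate correlations and a multivariate adjusted R-squared
    audit); four strategies for applying confound removal to out-of-sample
    data under covariate and confound shift; regional-homogeneity (Kendall's
    W) and functional-connectivity (Fisher-z) feature extraction from ROI
    time-series; and a synthetic generator of confounded datasets with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
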