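Package: themescan
Title: Iterative Thematic Categorization of Regularized-Model Features for
    Wide Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for finding interpretable groups of predictors of a binary
    outcome in very wide one-hot-encoded survey data. Implements a lasso
    feature-selection stage feeding a ridge logistic refit and a feed-forward
    neural network, ROC-AUC and balanced-error-rate evaluation at a fixed
    decision threshold, knee-point (maximum-curvature) selection of meaningful
    features from the sorted coefficient curve, and an iterative thematic
    categorization procedure in which expert-coded themes are qualified,
    the dominant theme's features are removed, and models are refit until no
    new themes emerge. Includes a synthetic survey generator with planted
    thematic effects, outcome-prevalence calibration, and latent-copula
    masking between themes, so that the whole pipeline can be validated with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
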