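Package: gmnsc
Title: Nearest Shrunken Centroid Classifiers for Class-Imbalanced
    High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the nearest shrunken centroid (NSC) family of
    high-dimensional classifiers - PAM (uniform soft-thresholding), ALP
    (adaptive L-infinity-norm penalty) and AHP (adaptive hierarchical
    penalty) - together with their GM variants, which tune the shrinkage
    threshold by maximising the cross-validated geometric mean of the
    class-specific predictive accuracies (g-means) instead of minimising
    the overall error rate. Minimising the overall cross-validated error
    biases NSC classifiers towards the majority class when the data are
    class-imbalanced; g-means tuning removes most of that bias while
    selecting far fewer variables. Includes stratified cross-validated
    threshold tuning, test-set evaluation (per-class accuracy, g-means,
    AUC, variable-selection FDR/FNR), a block-exchangeable multivariate
    Gaussian simulation engine for imbalance experiments, minority
    over-sampling, delimited-text I/O, model persistence and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
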