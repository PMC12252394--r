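Package: nitrospec
Title: Classifying Nitrogen-Efficient Wheat Varieties from Canopy Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for classifying nitrogen-efficient wheat
    varieties from UAV canopy hyperspectral reflectance. Computes the eight
    agronomic nitrogen-efficiency indices from field phenotypes, derives
    per-variety efficiency labels by t-SNE embedding and complete-linkage
    hierarchical clustering anchored on reference varieties, selects
    characteristic wavelengths with a Lasso screen refined by competitive
    adaptive reweighted sampling (CARS) over partial least squares models,
    and classifies canopy spectra with a serial SVM to gradient-boosted-tree
    fusion, evaluated by overall accuracy and Cohen's kappa under stratified
    ten-fold cross-validation. Includes a synthetic spectra and phenotype
    generator emulating the field-trial design for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    e1071,
    xgboost,
    randomForest,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
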