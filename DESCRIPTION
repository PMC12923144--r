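Package: oceansdm
Title: Ensemble Habitat Suitability Modelling for Marine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for marine species distribution
    modelling: harmonisation and quality flagging of multi-source occurrence
    records, three-axis (bottom/coast/surface) habitat classification,
    construction of biogeographical and potential range masks from expert
    range maps or biogeographic provinces, environmental-space thinning,
    habitat-aware pseudo-absence generation, a ten-algorithm ensemble fitted
    under environmentally blocked cross-validation with TSS gating, and
    projection onto present and future climate scenarios with uncertainty
    (committee average, coefficient of variation, clamping) and range-change
    indices. Ships a synthetic-world generator with known true niches so the
    whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    MASS,
    mgcv,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    geosphere,
    jsonlite,
    knitr,
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
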