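Package: pfasorption
Title: Predicting PFAS Solid-Liquid Distribution Coefficients in Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting solid-liquid distribution coefficients
    (Kd) of per- and polyfluoroalkyl substances (PFAS) in soils and
    sediments. Implements pH-dependent speciation descriptors
    (Henderson-Hasselbalch abundances, effective molecular weight and
    charge density), harmonization of heterogeneous literature sorption
    records (Kd from Koc or from Freundlich/Langmuir isotherm fits,
    outlier screening against the log Koc - log Kow trend), nan-aware
    K-nearest-neighbour imputation of missing soil properties, a
    two-layer stacking ensemble (ridge, random forest, extremely
    randomized trees and gradient boosting under a multi-layer
    perceptron meta-model), evaluation metrics (NRMSE, CV-NRMSE, RPD,
    residual diagnostics), exact Shapley and partial-dependence
    sensitivity analysis, descriptive log Koc analyses by chain length
    and functional group, and batch prediction over gridded soil
    property tables to produce tabular Kd maps. Synthetic-data
    generators make the whole pipeline testable offline.
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
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
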