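Package: viscQSPR
Title: Temperature-Dependent Viscosity QSPR Modeling with Physics-Informed Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative structure-property relationship
    (QSPR) modeling of temperature-dependent liquid viscosity. Curates
    (SMILES, temperature, viscosity) records with element/fragment,
    box-and-whisker and positive-temperature-deviation filters; builds
    descriptor matrices from 2D physicochemical descriptors, hashed circular
    fingerprints, element-composition statistics and inverse temperature;
    benchmarks eight regression algorithm families as bagged ensembles under
    compound-disjoint resampling with a generalization-gap model score;
    attributes predictions with Shapley values; and extracts eight molecular
    dynamics trajectory descriptors (density, free volume, radius of gyration,
    Hansen solubility parameters, heat of vaporization, RMS displacement).
    Includes a synthetic Vogel-equation data generator so the whole pipeline
    is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    mixOmics,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
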