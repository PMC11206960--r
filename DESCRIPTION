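Package: caco2qspr
Title: QSPR Modelling of Caco-2 Apparent Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-property relationship (QSPR) pipeline for
    predicting apparent permeability (log Papp) across Caco-2 cell monolayers
    from molecular descriptors. Provides fit-on-training preprocessing (median
    imputation, near-zero-variance and pairwise-correlation filtering,
    centering and scaling), descriptor selection by recursive feature
    elimination refined with a genetic algorithm, five regression models
    (multiple linear regression, partial least squares, radial-kernel support
    vector machine, random forest, gradient boosting) plus a linear stacking
    ensemble, a leverage-based applicability domain with Williams-plot export,
    permeability classification, and rule-based drug-likeness scoring. A
    seeded synthetic-data generator reproduces the statistical structure the
    pipeline assumes so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ranger,
    kernlab,
    xgboost,
    mixOmics,
    ChemmineOB,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
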