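Package: metabgxe
Title: Strain-Aware Analysis of Diet-Induced Metabolomic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting diet effects on untargeted metabolomics
    profiles in genetically divergent mouse panels (e.g. Collaborative Cross
    strains), where strain main effects can mask treatment effects.
    Implements run-day median normalization, unit-median rescaling and
    minimum-value imputation; per-metabolite ordinary-least-squares strain
    residualization; orthogonal partial least squares discriminant analysis
    (OPLS-DA) with cross-validated Q2, label-permutation significance (pQ2),
    predictive/orthogonal VIP scores and rmsVIP feature selection;
    strain-stratified fold-change statistics with assumption-gated univariate
    tests and Tukey-Kramer compact letter displays; and hypergeometric
    over-representation analysis of selected metabolites against
    user-supplied metabolite sets. Includes a synthetic-data generator
    emulating a strain-by-diet study design for power and calibration checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
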