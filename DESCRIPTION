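Package: acnrisk
Title: Race-Stratified Risk Prediction of Advanced Colorectal Neoplasia
    with Neighbourhood Deprivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating risk prediction models of
    advanced colorectal neoplasia (ACN) stratified by race, and for
    quantifying the contribution of neighbourhood socioeconomic
    deprivation to risk.  Implements bootstrap-stability predictor
    selection around fixed-effect logistic regression fitted by
    iteratively reweighted least squares, an Area Deprivation Index (ADI)
    constructed as the first principal component of 17 census-tract
    socioeconomic indicators scaled to 0-100, a two-stage augmentation of
    base-model risk predictions with ADI and census-tract random
    intercepts fitted by adaptive Gauss-Hermite quadrature, calibration
    (Hosmer-Lemeshow) and discrimination (C-statistic with bootstrap
    confidence intervals) metrics, a Cochran-Armitage prevalence trend
    test across deprivation quantiles, and a variance-partition statistic
    for the share of tract-level risk variation explained by ADI.  A
    synthetic multilevel cohort generator emulating a two-race screening
    colonoscopy population nested in census tracts supports end-to-end
    simulation studies and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
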