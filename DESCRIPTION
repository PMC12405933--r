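Package: exacnet
Title: Bayesian Network Prediction Pathways for Severe Asthma Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to learn, validate and interrogate discrete Bayesian
    networks that describe the prediction pathway from clinical predictors
    (demographics, type-2 inflammation biomarkers, lung function, medication
    use, comorbidities and exacerbation history) to future severe asthma
    exacerbations. Includes a synthetic severe-asthma cohort generator with a
    configurable ground-truth pathway network, registry-style preprocessing
    (zero/outlier recoding, iterative random-forest imputation, mutual-
    information preserving discretization, adaptive synthetic rebalancing),
    seven constraint- and score-based structure learners with bootstrap
    consensus averaging under expert constraints, exact inference with
    do-interventions and counterfactual comparison, influence-diagram
    evaluation, and internal-external validation with discrimination and
    calibration metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
LinkingTo: Rcpp
Config/testthat/edition: 3
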