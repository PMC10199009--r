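Package: travelCAR
Title: Area-Level Travel Behaviour Metrics and Bayesian Conditional
    Autoregressive Spatial Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ecological analyses linking travel-diary surveys to
    small-area health outcomes. Classifies each participant's survey-day trip
    legs into duration-based travel categories (active, mixed, sedentary,
    no travel) and mode-based groups, aggregates participants into area
    profiles (category shares, normalised Shannon-entropy travel-mode
    diversity, sociodemographic covariates, population-weighted deprivation
    scores), builds border-contiguity adjacency matrices, and fits Gaussian
    Bayesian conditional autoregressive regressions with the Leroux prior via
    a purpose-built MCMC sampler, including compositional substitution
    models. A synthetic travel-survey generator with known ground-truth
    parameters supports validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
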