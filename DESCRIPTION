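Package: fertgibbs
Title: Fertility Traits from On-Farm AI Service Records and Bayesian
    Genetic Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives heifer and cow fertility traits (age at first service
    and first calving, services per conception, calving to first service,
    days open, and binary success traits) from on-farm artificial
    insemination service records, with the editing rules, seasons and
    herd-year-season contemporary groups used in dairy genetic evaluation.
    Computes pedigree inbreeding coefficients, the numerator relationship
    matrix A and its sparse inverse by Henderson's rules, and estimates
    heritabilities plus genetic and phenotypic correlations under
    multi-trait linear and threshold (liability) animal models by Gibbs
    sampling, with an average-information REML fitter for linear traits as
    an independent cross-check and an event-level herd simulator for
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
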