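Package: matchedme
Title: Bayesian Measurement Error Correction for Individually Matched
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects odds-ratio estimates for classical additive measurement
    error in multiple continuous exposures in individually matched (1:M)
    case-control studies. Combines a conditional logistic disease model, a
    normal measurement model with known diagonal error covariance, and a
    two-level multivariate-normal random-effect exposure model in a joint
    Bayesian analysis fitted by a compiled Metropolis-within-Gibbs sampler.
    Includes a delta-method estimator of assay error variance from
    percent-recovery quality-control data, a naive (error-ignoring)
    comparator, sensitivity sweeps over the assumed error magnitude, and a
    synthetic-data generator with the matched-set structure the model assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
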