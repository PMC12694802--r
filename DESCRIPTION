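Package: srscape
Title: Bayesian Additive Regression Tree Isoscapes for Bioavailable Strontium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building predictive isoscapes of the radiogenic
    strontium isotope ratio (87Sr/86Sr) from georeferenced environmental
    samples and gridded geo-environmental covariates. Provides sample-table
    ingestion and quality filters, a bounded logit transform for ratio
    responses, domain-blocked principal component reduction of covariate
    stacks, a from-scratch Bayesian Additive Regression Trees (BART)
    sampler with full posterior uncertainty, gridded isoscape prediction
    with uncertainty layers, region-holdout evaluation metrics, and
    posterior-predictive assessment of tissue values against a site's
    predicted local range. A synthetic-landscape generator with stored
    ground truth supports recovery, coverage, and calibration testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    readr,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
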