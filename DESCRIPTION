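Package: prevfuse
Title: Bayesian Multi-Source Estimation and Forecasting of Disaggregated Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines survey estimates, administrative case counts, and
    cross-country panels of prevalence estimates in a single Bayesian
    hierarchical model of disaggregated prevalence. The system model is a
    binomial count layer over a logit-scale linear predictor with
    damped-linear-trend priors on time terms; each data source has an
    explicit measurement-error data model (unbiased normal for design-based
    survey estimates, log-scale age-biased normal for administrative
    counts). Includes extraction of informative trend hyperpriors from an
    international panel, calibration of a scaled inverse-chi-squared prior
    for the administrative error variance, joint MCMC estimation with
    integrated interpolation and forecasting, replicate-data model checks,
    and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    generics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
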