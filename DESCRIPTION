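Package: phylopcm
Title: Phylogenetic Comparative Methods for Species-Level Disease Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing species-level disease-prevalence traits on
    time-calibrated phylogenies. Fits seven continuous-trait evolution models
    (Brownian motion, Ornstein-Uhlenbeck, Pagel's lambda, delta and kappa,
    white noise, and a linear rate trend) by maximum likelihood using a
    linear-time structured-covariance algorithm, selects among them by AIC
    with a configurable decisive-support threshold, reconstructs ancestral
    states with confidence intervals, and runs phylogenetic regressions that
    propagate binomial sampling error in prevalence estimates: Brownian
    PGLS with sampling error, PGLS with jointly estimated Pagel's lambda,
    and a model-selected PGLS that conditions the regression on the
    AIC-best evolution model. Includes a phylogenetic binomial GEE and a
    simulation benchmark comparing false-positive and false-negative rates
    of the regression methods across generating models, species counts and
    minimum-record thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phytools,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
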