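Package: cerebnorm
Title: Hierarchical Bayesian Normative Models of Cerebellar Growth
Version: 1.0.0
Authors@R:
    person("cerebnorm", "developers", email = "cerebnorm@example.org",
           role = c("aut", "cre"))
Description: Normative growth modelling of region-wise cerebellar
    morphometrics (volumes, grey- and white-matter densities) in
    longitudinal pediatric cohorts.  Fits hierarchical Bayesian
    regressions with a sinh-arcsinh (SHASHb) likelihood and partial
    pooling of intercept, slope and scale over batch cells (sex by
    scanner), computes batch-free deviation z-scores and growth bands
    for held-out scans, tests anterior-posterior growth gradients with
    Benjamini-Hochberg correction, and compares extreme-deviation rates
    between subgroups with exact one-sided binomial tests.  Includes a
    longitudinal cohort simulator so the full pipeline is testable
    without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
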