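Package: keypopsize
Title: Population Size Estimation for Hidden Key Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of the size of hidden (hard-to-reach) populations
    from multiplier and capture-recapture designs: service and unique-object
    multipliers with RDS-II (inverse network degree) weighted survey
    proportions, classical two-source Lincoln-Petersen and Chapman
    estimators, and a Bayesian nonparametric latent-class capture-recapture
    model for three or more capture sources fitted by Gibbs sampling under a
    truncated stick-breaking Dirichlet-process prior. Includes a synthetic
    hidden-population and respondent-driven-sampling simulator with
    configurable violations of the classical capture-recapture assumptions,
    so that every estimator can be validated against a known true size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
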