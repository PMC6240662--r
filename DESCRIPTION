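Package: domclpe
Title: Asymmetric IRT Calibration of Discrete-Option Multiple-Choice Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian calibration of discrete-option
    multiple-choice (DOMC) item responses. Options are administered one at a
    time in random order, so the scheduled number of response options k varies
    across administrations of the same item; the package models the resulting
    key-location effects with Samejima's logistic positive exponent (LPE)
    model and with two-parameter logistic (2PL) comparison models whose
    parameters vary with k. Provides a DOMC administration simulator with
    conjunctive option-level scoring, Metropolis-within-Gibbs samplers for
    five competing models, Gelman-Rubin convergence diagnostics, deviance
    information criterion (DIC) model comparison, classical item statistics by
    key location, and latent-metric shrinkage diagnostics contrasting
    symmetric and asymmetric calibrations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
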