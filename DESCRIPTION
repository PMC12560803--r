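Package: larvastat
Title: Dose-Response Statistics for Larval Zebrafish Locomotion and MEA
    Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipelines for two neurotoxicology assays: the larval
    zebrafish light-dark transition test (two-minute activity binning,
    unit-interval scaling, a logit-link beta generalized additive mixed model
    with penalized time smooth and per-larva random intercepts, estimated
    marginal means with single-step Tukey-style adjustment and compact letter
    displays, and the visual startle response with its Gaussian linear mixed
    model) and microelectrode-array spike-count pharmacology (activity and
    percentile inclusion filters, agonist/antagonist unit classification,
    per-unit normalization, and Friedman/Conover many-to-one testing with
    Benjamini-Hochberg adjustment). Includes synthetic-data generators that
    reproduce the statistical structure of both assays so every stage is
    testable without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    mgcv,
    stats,
    utils
Suggests:
    emmeans,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
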