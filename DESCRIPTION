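Package: discountDDM
Title: Reliability Analysis of Hierarchical Drift-Diffusion Models of Temporal Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for assessing the test-retest reliability of
    temporal discounting measures across testing contexts. Provides generative
    simulation of intertemporal choices and response times, hierarchical
    Bayesian estimation of hyperbolic discounting combined with softmax or
    drift-diffusion (Wiener first-passage-time) choice rules, DIC model
    comparison, model-free indifference-point and area-under-curve summaries,
    intraclass-correlation and split-half reliability statistics, directional
    Bayes factors for session contrasts, and phase-binned electrodermal
    activity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
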