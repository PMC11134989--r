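Package: eventdep
Title: Stochastic Dependency of Event Elements in Episodic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent-trait analysis of stochastic dependency in cued-recognition
    memory data. Fits a simplified three-parameter logistic item response model
    with fixed discrimination and fixed guessing by marginal maximum likelihood,
    and its bifactor extension with equality-constrained event-specific trait
    variances. Quantifies within-event retrieval dependency with Yen's Q3
    residual correlations summarised into the dependency measure D, tests D
    against zero and between-condition differences in D by parametric bootstrap,
    and performs simulation-based a priori power analysis for the difference
    test. Includes a synthetic-data generator that emulates multi-element
    cued-recognition experiments with a bifactor latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
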