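Package: specdcm
Title: Dynamic Causal Modelling of EEG Cross-Spectral Densities for a
    Cortical Grasping Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linearized neural-mass network models to EEG
    cross-spectral densities by variational Laplace, compares models across
    subjects with random-effects Bayesian model selection, aggregates
    subject-level effective connectivity with parametric empirical Bayes and
    Bayesian model reduction, and predicts age and precision-grip
    performance from coupling estimates by leave-one-out cross-validation.
    Includes a synthetic-cohort generator with known ground truth for
    end-to-end recovery testing, plus scoring and group statistics for
    precision-grip force traces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
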