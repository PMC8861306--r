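Package: brainstates
Title: Dynamic Brain-State Analysis with Variational Bayes Gaussian Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multi-subject region-of-interest (ROI) fMRI time
    series into recurring whole-brain states with a variational Bayes
    Gaussian hidden Markov model (HMM).  Provides per-subject ROI
    standardization, cohort concatenation and principal component
    reduction, HMM fitting with free-energy monitoring, model-order
    selection by the median fractional-occupancy elbow, per-subject
    temporal statistics (fractional occupancy, lifetimes, interval
    times), covariate-adjusted two-sample group comparison with
    Bonferroni control, and Newman spectral community detection on the
    thresholded state-transition matrix.  Includes a synthetic-cohort
    generator with planted states, group effects and transition
    communities so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
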