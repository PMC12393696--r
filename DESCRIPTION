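Package: mgmtperf
Title: Management Practices and Health-Facility Performance Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the association between management practices
    and the performance of community-based organizations (CBOs) delivering
    HIV services. Builds inverse-covariance-weighted (GLS) management
    indices from binary practice items, adjusts them for contextual
    characteristics, estimates mean associations by OLS with
    heteroskedasticity-robust standard errors, decomposes explained
    variance across management domains by Shapley (Shorrocks) values, and
    estimates quantile-regression effects with paired-bootstrap
    cross-quantile equality tests. Includes a calibrated synthetic CBO
    panel generator with known ground truth so every stage of the pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
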