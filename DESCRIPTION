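Package: mnormcomp
Title: Multilevel Multivariate Normative Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using aggregated normative databases in
    which healthy-control data from many studies are pooled, tests are
    missing by design, and scores depend on age, gender and education.
    Fits a three-level model (test scores within participants within
    studies) by full-information maximum likelihood with an unstructured
    within-study covariance and diagonal between-study covariance, and
    compares a patient's profile of test scores to covariate-matched norms
    with an adapted Hotelling T-squared statistic, one-sided decision rules
    and univariate comparisons with or without Bonferroni correction.
    Includes a Monte Carlo engine for type-I-error and sensitivity studies
    under planned-missingness designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nlme,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
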