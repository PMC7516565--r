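Package: ssgic
Title: Two-Stage Screening-Selection for High-Dimensional Binary Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection for binary regression with many more
    predictors than observations, robust to misspecification of the
    response function. A first screening stage fits an l1-penalized
    empirical-risk minimizer (logistic, quadratic or Huber loss) over a
    grid of penalties; the nonzero coefficients are ordered by magnitude
    into nested families of candidate supports, and a second stage picks
    the support minimizing a Generalized Information Criterion (AIC, BIC
    or extended BIC). Includes the single-penalty (SS), multi-penalty
    union (SSnet), cross-validated (SSCV) and Lasso plug-in (LFT)
    selectors, simulators for correctly specified and misspecified
    single-index benchmark designs with AR(1)-correlated Gaussian
    predictors, selection-performance metrics (angle, inclusion, equality
    and superset rates), and diagnostics for the restricted-eigenvalue
    cone condition and the Lasso separation property.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
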