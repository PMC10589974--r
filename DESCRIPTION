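Package: spatstar
Title: Bayesian Spatially Structured Additive Logistic Regression for
    Small-Area Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for district-level analysis of binary survey outcomes such
    as intimate partner violence in Demographic and Health Survey (DHS) style
    data. Implements survey-weighted prevalence estimation with Taylor
    linearization, design-based (Rao-Scott) chi-square tests, conventional
    logistic screening, and a fully Bayesian structured additive logistic
    regression with a P-spline smooth for age, an intrinsic conditional
    autoregressive (CAR) structured district effect plus an exchangeable
    unstructured effect (the Besag-York-Mollie convolution), fitted by a
    Polya-Gamma augmentation Gibbs sampler. Includes the structured-share
    variance decomposition, deviance information criterion, global and local
    Moran's I with permutation inference, bivariate choropleth
    classification, district adjacency graph input/output, and a synthetic
    DHS-like data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
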