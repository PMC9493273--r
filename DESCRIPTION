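Package: soilnorm
Title: Soil-Augmented Reaction-Norm Models for Genomic Prediction in
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian multi-kernel GBLUP models for yield prediction in
    plant breeding trials conducted across environments that differ in
    soil texture.  Fits the main-effect GBLUP model and reaction-norm
    extensions in which marker-by-environment and marker-by-soil
    interactions enter through Hadamard products of covariance
    structures.  Variance components are estimated by Gibbs sampling
    with conjugate scaled-inverse-chi-square priors.  Includes the four
    cross-validation schemes used in breeding programs (tested/untested
    genotypes in observed/unobserved environments), per-environment and
    inverse-variance-weighted correlation summaries, percentile
    classification grids, and a simulator of unbalanced soybean-like
    multi-environment trial data with known variance components.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
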