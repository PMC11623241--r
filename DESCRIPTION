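Package: mdnrm
Title: Bayesian Multidimensional Nominal Response Models for Multiclass
    Observer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the family of multidimensional nominal response models
    (MDNRM) used to evaluate raters in multiclass diagnostic observer
    studies, for example radiologists classifying chest CT cases as
    normal, non-COVID pneumonia, or COVID pneumonia.  Six model variants
    are provided: the conventional two-parameter nominal response model,
    its one-parameter reduction, the original MDNRM whose ability
    parameter is a ground-truth-by-response matrix per rater, and three
    two-parameter MDNRM subtypes that add discrimination parameters.
    Inference is full Bayesian MCMC via a built-in No-U-Turn sampler with
    adaptive step size and diagonal mass matrix.  Model comparison uses
    the widely applicable information criterion (WAIC) and Pareto-smoothed
    importance-sampling leave-one-out cross-validation (PSIS-LOO); rater
    abilities are compared with the probability of direction and highest
    density intervals.  A simulator generates synthetic observer-study
    data from the same generative models for testing and parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
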