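Package: psivox
Title: Bayesian Adaptive Psychophysics and Permutation-Based Voxelwise Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating asynchronous saccadic-choice psychometric
    functions with a Bayesian adaptive (psi-method) procedure, simulating
    observers with tunable delta-independent volitional interference, and
    relating the estimated slope to white-matter diffusivity surrogates by
    masked voxelwise general linear models with Freedman-Lane permutation
    inference, variance smoothing, threshold-free cluster enhancement (TFCE)
    and cluster-extent reporting. Includes generators for synthetic
    skeleton-masked imaging cohorts with planted slope-diffusivity effects,
    parameter-recovery and interference-sweep study harnesses, and a
    config-driven pipeline writing CSV/JSON/NIfTI artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
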