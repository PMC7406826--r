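Package: rsfcmed
Title: Seed-Based Resting-State Connectivity Mediation with Permutation
    Cluster Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how seed-based resting-state functional
    connectivity mediates a behaviour-symptom relationship. Implements the
    post-realignment fMRI cleaning chain (motion quality control and
    exclusion, Friston-24 and spike nuisance regressors, CompCor components,
    Gaussian smoothing, band-pass filtering), hippocampal-style subregion
    seed definition with Fisher-z seed-to-voxel connectivity maps, voxel-wise
    three-path mediation with bias-corrected bootstrap inference,
    cluster-extent family-wise error correction by subject permutation with
    Freedman-Lane covariate handling, and a Monte Carlo power analysis for
    indirect effects. A synthetic-cohort generator plants known path
    coefficients in simulated 4D images so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
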