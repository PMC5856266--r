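Package: roimvpa
Title: Simulation and Region-of-Interest Multivoxel Pattern Analysis of
    Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully simulated multivoxel pattern analysis
    (MVPA) pipeline for task fMRI. Generates multi-subject, two-session
    BOLD datasets with known ground truth (epoch designs with jittered
    blanks, canonical double-gamma haemodynamics, planted multivoxel
    domain codes and univariate magnitude confounds), fits per-voxel
    general linear models with run-wise condition regressors, localizes
    regions of interest by peak thresholding with permutation-based
    cluster-extent correction, decodes condition domain from beta
    patterns with a linear support vector machine under
    leave-one-run-out cross-validation, calibrates significance with
    label-permutation null distributions, and provides cross-session
    transfer, feature-count curves, beta-magnitude confound diagnostics,
    and repeated-measures group statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
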