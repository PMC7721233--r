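Package: opponency
Title: Motion-Opponency fMRI Analysis with Multivariate Pattern Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying motion opponency in human visual cortex with
    block-design fMRI. Generates paired-dot Glass-pattern stimuli (in-phase,
    counter-phase, and nonmotion flicker conditions) with verifiable
    motion-energy balance, simulates multi-run voxel time series with a
    controllable condition-pattern geometry, estimates block-wise beta series
    with an ordinary least squares GLM and a double-gamma haemodynamic
    response, decodes condition pairs with leave-one-run-out linear support
    vector machines, measures cross-decoding misclassification bias, and
    performs group inference with within-run label-permutation nulls plus
    univariate repeated-measures statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
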