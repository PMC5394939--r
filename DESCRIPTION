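Package: prfdecode
Title: Population Receptive Field Models and Stimulus Position Decoding for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a randomly moving visual stimulus, generates synthetic
    fMRI-like voxel populations with area-specific Gaussian receptive-field
    geometry, fits six-parameter population receptive field (pRF) models per
    voxel by maximum likelihood, decodes stimulus position from multivoxel
    amplitudes by grid maximum likelihood and by kernel support-vector
    regression under leave-one-run-out cross-validation, and computes
    population-level summaries: per-axis decoding accuracy, receptive-field
    centre spread, matched-voxel-count subsampling, and distance-exclusion
    decay analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
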