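Package: preplayr
Title: Preplay-Like Pattern Reactivation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spontaneous reactivation of stimulus-specific multivoxel
    patterns in resting-state fMRI and relates it to behavioural understanding
    ratings. Per-sentence neural representations are extracted as first-level
    GLM t-statistic maps from block-design induced sessions; reactivation
    intensity is the mean of the top-N Fisher-Z-transformed per-frame pattern
    correlations in resting data, with a variance-decomposition estimator for N;
    per-subject intensity-rating correlations are merged across subjects with
    sample-size-weighted Fisher-Z meta-analytic statistics and tested against
    zero; a cube searchlight with max-statistic permutation inference maps the
    effect voxelwise. A seeded synthetic-cohort generator with known ground
    truth makes the whole pipeline testable end to end.
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
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
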