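Package: boldicc
Title: Test-Retest Reliability of fMRI GLM Pipelines on Synthetic BOLD Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-subject, two-session BOLD fMRI cohorts with known
    ground-truth activation reliability and noise structure, fits four
    first-level general linear model pipelines that differ in hemodynamic
    response basis flexibility and physiological-noise correction (canonical
    HRF block model, temporal+dispersion derivative bases, a single pooled
    mCompCor nuisance regressor, and their combination), tests the fitted
    models' residual assumptions voxelwise (Shapiro-Wilk, Breusch-Pagan,
    Durbin-Watson), estimates voxelwise ICC(3,1) test-retest reliability maps
    with median-voxel region summaries, and compares pipelines with Friedman
    and Nemenyi rank tests.
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
    generics,
    jsonlite,
    readr,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    igraph,
    optparse
Config/testthat/edition: 3
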