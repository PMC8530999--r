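Package: varpls
Title: BOLD Signal Variability and Partial Least Squares Brain-Behavior Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping resting-state BOLD signal variability onto
    dimensional clinical phenotypes. Converts motion-annotated fMRI
    time-courses into z-scored voxelwise variability maps (nuisance
    regression, band-pass filtering, framewise-displacement scrubbing,
    minimum-duration gating), residualizes them on demographic and scanner
    confounds, and fits a partial least squares (PLS) correlation model
    linking the maps to behavioral scales. Inference uses group-restricted
    permutation of the behavioral data for component significance and
    group-restricted bootstrap resampling for loading reliability, both with
    procrustes alignment of resampled singular structure. Includes a
    synthetic-cohort generator with planted latent brain-behavior structure
    for calibration and parameter-recovery studies, a post-hoc statistical
    battery with false-discovery-rate control, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
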