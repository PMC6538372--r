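Package: lamod
Title: Laminar fMRI Analysis of Top-Down and Bottom-Up Response Modulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cortical-depth-resolved analysis of block-design BOLD fMRI:
    spatial unmixing of voxel time courses into depth-bin time courses via
    partial-volume depth weights, per-layer normalization, quantification of
    feature-based attention and stimulus-contrast modulations across gray
    matter depth (agranular-granular scores), repeated-measures ANOVA with
    Huynh-Feldt correction, and within-subject error bars.  Includes a
    synthetic laminar-BOLD cohort generator with known ground truth
    (layer-specific effects, draining-vein bias, AR(1) plus drift noise) and
    a QUEST Bayesian adaptive staircase with simulated psychophysical
    observers, so the full pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
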