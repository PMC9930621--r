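Package: vaparc
Title: Functional Parcellation of the Auditory Cortical Voice Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for splitting the auditory
    cortical voice area into core, acoustic and accessory subfields. Synthesizes
    voice and nonvoice sound tokens and five classes of acoustic equivalents
    (envelope/spectrum chimeras, temporally scrambled sounds, pitch/amplitude
    contour sounds, dynamic moving ripples and Gaussian sound textures), extracts
    an 88-slot acoustic feature set with support-vector classification, builds
    block fMRI designs with canonical two-gamma haemodynamic responses and
    RETROICOR-style physiological regressors, fits voxel-wise general linear
    models with interaction and conjunction contrasts and a scaled
    voice-selectivity criterion, runs searchlight multivoxel pattern analysis
    with leave-one-run-out cross-validation and cross-classification, and
    assembles the resulting parcellation with per-hemisphere coverage statistics
    and effect sizes. A seeded synthetic-cohort generator with ground-truth voxel
    classes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    RNifti,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
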