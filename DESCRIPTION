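Package: fcnet
Title: ROI-Network Resting-State Functional Connectivity with Group ANCOVA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for seed-sphere region-of-interest (ROI) functional
    connectivity analysis of resting-state BOLD data across three brain
    networks (cingulo-opercular, default mode, and
    orbitofrontal-striatal-thalamic). Extracts mean time courses from 5-mm
    spherical ROIs in MNI space, computes Fisher r-to-z transformed
    ROI-to-ROI correlation matrices, reduces them to six within- and
    between-network connectivity metrics per subject, and compares groups
    with one-way ANCOVA (age and mean framewise displacement covariates),
    partial eta squared effect sizes, Benjamini-Hochberg false-discovery-rate
    correction, and Fisher's least-significant-difference post-hoc contrasts.
    Includes a seedable block-covariance cohort simulator for end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    optparse
Config/testthat/edition: 3
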