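Package: vasomap
Title: Laminar VASO and BOLD Digit-Mapping Analysis with a Synthetic Cortical Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for layer-resolved (laminar) functional MRI of
    digit representations in somatosensory cortex using interleaved
    blood-nulled (VASO) and BOLD acquisitions. Covers preprocessing of
    interleaved nulled/not-nulled time series (steady-state volume
    replacement, 7th-order temporal upsampling, nulled/BOLD alignment and
    dynamic division for BOLD correction), quality maps (tSNR, T1-weighted
    EPI, framewise displacement), equivolume cortical depth estimation and
    layer binning, geodesic gray-matter disks and distance maps, voxelwise
    general linear models with gamma haemodynamic response and
    Benjamini-Hochberg thresholding, winner-take-all digit region-of-interest
    construction with columnar depth propagation, model-free event-related
    averaging in layer and distance-bin compartments, and extraction of
    triphasic response features (initial peak, trough, post-stimulus peak).
    Includes a synthetic cortical-ribbon phantom with analytically known
    equivolume depth and injected laminar and triphasic ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
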