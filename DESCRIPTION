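Package: beadct
Title: Morphometric Analysis of Microcarrier Beads in Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative 3D image analysis of microcarrier beads imaged by
    (contrast-enhanced) micro-computed tomography. Provides staining-aware
    multilevel Otsu binarization, detection of spherical beads by a 3D Hough
    transform, a pore-sealing/watershed pipeline that isolates individual
    porous or concave beads, per-bead morphometrics (convex-hull pore
    decomposition, porosity, equivalent diameter, principal axis lengths,
    Crofton surface area, accessible-surface profiles as a function of probe
    radius), cohort-level statistics (swelling, surface area per dry weight,
    distribution tests), a validation harness for comparing segmentations,
    and a synthetic phantom generator with exhaustive voxel ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
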