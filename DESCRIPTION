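Package: voxdosim
Title: Voxel-Scale Dosimetry for Alpha- and Beta-Emitter Radiopharmaceutical
    Therapy in Tumor/Fibroblast Microenvironments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds voxelized spherical tumor models in which tumor cells and
    cancer-associated fibroblasts (CAFs) are interspersed at controlled degrees
    of clustering, and computes absorbed-dose microdistributions for the beta
    emitter Lu-177 (dose-voxel-kernel convolution/superposition) and the alpha
    chain emitter Ac-225 (straight-track continuous-slowing-down Monte Carlo of
    the full decay chain). Quantifies dose heterogeneity with cumulative
    dose-volume histograms, efficacy ratios (mean target dose over mean
    whole-mass dose), threshold-fraction statistics, and axis-raycast
    nearest-CAF distance fields, and includes a 2D immunohistochemistry-style
    analysis chain on synthetic stained-section images. Nuclear decay schemes
    and charged-particle stopping powers for soft tissue ship as plain-text
    data tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    png
Config/testthat/edition: 3
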