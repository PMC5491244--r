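Package: bnctplan
Title: Multi-Field Treatment Planning and Dosimetric Evaluation for Boron
    Neutron Capture Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthetic voxel head phantoms, a calibrated four-component
    epithermal neutron beam dose model, RBE/CBE weighting of the thermal,
    fast, photon and boron-capture dose components, multi-field beam weight
    balancing, prescription normalization, dose-volume-histogram metrics and
    a cohort driver for comparing two-, three- and four-field boron neutron
    capture therapy plans for deep-seated brainstem targets.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
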