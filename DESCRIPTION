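Package: phasedheat
Title: Phased-Array Hyperthermia Applicator Modelling and SAR Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel dielectric modelling of clinical phased-array hyperthermia
    applicators (AMC-2 and AMC-4/ALBA-4D waveguide systems, BSD Sigma-30 and
    Sigma-60 annular dipole arrays) and their quality-assurance phantoms.
    Computes per-antenna steady-state electromagnetic fields with a
    finite-difference time-domain (FDTD) solver using convolutional perfectly
    matched layer boundaries, superposes them under phase-amplitude settings,
    and derives specific absorption rate (SAR) distributions, 1 cc-averaged
    SAR, measurement-axis profiles and focus metrics for comparison with
    published quality-assurance measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
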