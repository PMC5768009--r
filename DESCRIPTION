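Package: smcdose
Title: Simplified Monte Carlo Proton Dose Calculation with Large-Angle
    Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxelized simplified Monte Carlo (SMC) dose calculation for
    proton pencil-beam scanning. Particles are tracked voxel-to-voxel with
    Lynch-Dahl multiple Coulomb scattering and an optional single-interaction
    large-angle-scattering channel that reproduces the lateral low-dose halo.
    Dose is scored from integrated depth-dose (IDD) tables; when the
    large-angle channel is enabled, tables are first converted to modified
    IDD (m-IDD) form using a Monte Carlo estimate of the particle survival
    fraction so that laterally integrated dose is preserved. Includes
    analytic Bragg-curve IDD generation, phantom builders with slab
    heterogeneities, double-Gaussian beam phase-space sampling, scanned-field
    and spread-out-Bragg-peak plan construction, and an evaluation suite
    (depth-dose and off-center-ratio profiles, 2-D gamma index and pass
    rates).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
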