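Package: nirglucosim
Title: Skin Optics Simulation and Signal Analysis for Near-Infrared
    Non-Invasive Glucose Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying blood-flow interference in near-infrared
    non-invasive glucose measurement on skin. Provides a seven-layer skin
    optical-property model with chromophore absorption mixing and a
    Mie-theory power-law scattering perturbation, a layered Monte Carlo
    photon transport engine with ring detectors and a diffusion-dipole
    validation oracle, differential-absorbance spectral analytics
    (common-mode rejection, arm-elevation blood-spectrum extraction), oral
    glucose tolerance test (OGTT) correlation and RMSE statistics, and
    seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
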