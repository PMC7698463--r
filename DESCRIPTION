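Package: voxfluor
Title: Monte Carlo Fluorescence Photon Migration in Voxelized Breast-Tissue Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelized Monte Carlo simulation of excitation and
    fluorescence-emission photon migration in breast tissue for visible,
    near-infrared and shortwave-infrared fluorescence imaging. Provides
    tissue optical-property and fluorophore tables, segmentation of
    grayscale cryosection stacks into tissue labels, a synthetic breast
    phantom generator (contoured surface, two-voxel skin shell, branching
    duct tree), a compiled photon-transport engine (Henyey-Greenstein
    scattering, Fresnel boundary reflection, Russian roulette, fluence
    scoring), excitation-gradient fluorescence coupling, and surface
    detectability analysis with size and depth sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    yaml
Config/testthat/edition: 3
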