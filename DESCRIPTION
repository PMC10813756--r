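Package: vertfem
Title: Quantitative-CT-Based Finite-Element Simulation of Vertebral
    Compression Fractures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates anterior wedge compression fractures of isolated
    vertebral bodies from CT-like Hounsfield-unit volumes.  Provides
    synthetic vertebra phantoms, linear Hounsfield-unit-to-density
    calibration with a non-negativity floor, density-to-material power
    laws with an elastic-perfectly-plastic (von Mises) constitutive
    model, structured voxel-to-tetrahedron meshing with anatomical frame
    construction, a displacement-controlled quasi-static nonlinear
    finite-element solver with a rigidly coupled offset control point,
    extraction of stiffness, strength and plastic-strain fracture maps
    from load-displacement results, and model-versus-experiment
    comparison statistics including calibration of a yield-strain
    scaling factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
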