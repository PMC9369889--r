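Package: bonecal
Title: Calibrating Bone Density-Elasticity Laws from CT Voxel Models and
    Bending Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the coefficients of the power law
    E = a*(c*HU + b)^d that links computed-tomography Hounsfield units to
    the apparent density and Young modulus of cortical bone. Voxel grids of
    Hounsfield values are binned into density ranges, remeshed onto
    hexahedral grids aligned with the measured sample faces via the
    midpoint method, and simulated in linear-elastic three-point bending
    with eight-node brick elements. A real-coded genetic algorithm then
    minimizes the summed squared mismatch between simulated and measured
    bending stiffness across samples, subject to an upper bound on the
    Young modulus. A synthetic phantom generator provides ground-truth
    closed-loop experiments without CT scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
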