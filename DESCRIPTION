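Package: meniscusCDM
Title: Continuum Damage Mechanics Simulation of Meniscal Tensile Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tensile failure of fibrous soft tissue (human meniscus)
    with a transversely isotropic hyperelastic material coupled to scalar
    continuum damage mechanics. Provides the constitutive model
    (Veronda-Westmann ground substance, piecewise exponential-linear fiber
    network, quintic smoothstep damage evolution driven by von Mises stress or
    maximum normal Lagrange strain), a homogeneous uniaxial-stress driver, a
    total-Lagrangian quasi-static finite element solver on linear tetrahedra
    for 1/8-symmetry dogbone coupons, sequential Levenberg-Marquardt
    calibration of material and damage parameters to force-displacement
    curves, tear-region strain and tear-angle validation metrics, and a
    synthetic-data generator emulating experimental tensile curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
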