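Package: collacomp
Title: Compressive Mechanics and Remodeling of Collagen Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing collagen hydrogels under confined
    compression and the compressive remodeling they undergo around growing
    tumor spheroids. Implements a nonlinear biphasic (poroelastic)
    confined-compression model with a Yeoh solid matrix and constant
    isotropic Darcy permeability, including a forward consolidation solver
    and a two-step (equilibrium then transient) parameter-estimation
    procedure; continuous relaxation-time spectrum inversion of
    stress-relaxation decays by regularized non-negative least squares; a
    discrete three-dimensional fiber-network simulator with stretching and
    bending elasticity and force-threshold cross-link rupture; spheroid
    growth kinematics via the expanding-spherical-inclusion solution; and
    image quantification for second-harmonic-generation stacks and
    time-lapse spheroid frames (global thresholding, porosity, radial and
    axial intensity profiles, gel thickness, densified-layer detection,
    graininess-based radius tracking). Synthetic-data generators emulate
    every supported input class for fully reproducible recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
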