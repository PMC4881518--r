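Package: pmfpath
Title: Potentials of Mean Force from Targeted Molecular Dynamics and Umbrella Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes one-dimensional potentials of mean force (PMF) along physical
    reaction coordinates (torsion angle, mass-weighted RMSD, radius of gyration) by
    combining targeted molecular dynamics (TMD), harmonic umbrella sampling and the
    weighted histogram analysis method (WHAM). Ships a compiled Langevin dynamics
    engine with a minimal molecular-mechanics force field, collective variables with
    analytic gradients, window-selection and histogram diagnostics, a periodic and
    linear WHAM solver, RMSD-to-dihedral calibration with segment stitching, and
    trajectory-analysis operators (dynamical cross-correlation maps, hydrogen-bond
    occupancies, interhelical angles). Includes a united-atom butane fixture whose
    rotational free-energy profile serves as the worked example, and an analytic
    one-dimensional toy system for validating the WHAM solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
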