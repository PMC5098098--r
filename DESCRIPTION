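Package: eimsim
Title: Forward Modelling and Electrode-Placement Optimization for
    Electrical Impedance Myography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates tetrapolar electrical impedance myography (EIM)
    measurements on a multilayer anisotropic cylindrical limb model.
    Provides Cole-Cole dispersion models of tissue dielectric properties,
    a quasi-static complex-admittivity finite-volume forward solver on a
    conforming cylindrical tensor grid, closed-form and mesh-refinement
    verification oracles, sensitivity analyses of resistance and reactance
    to muscle and subcutaneous-fat thickness, and a bound-constrained
    genetic algorithm (stochastic uniform selection, arithmetic crossover,
    adaptive feasible mutation) that searches for the electrode
    configuration least sensitive to anatomical variation while retaining
    the ability to discriminate atrophied from normal muscle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
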