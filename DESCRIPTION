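Package: eitmon
Title: Electrical Impedance Tomography Simulation and Stroke-Monitoring
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and image-reconstruction toolkit for electrical
    impedance tomography (EIT) monitoring of intracerebral hemorrhage.
    Generates layered head phantoms with growing blood inclusions, solves
    the complete electrode model by the finite element method, and
    reconstructs conductivity changes with three algorithms: total
    variation regularized absolute imaging, linear difference imaging
    with a distance-based smoothness prior, and a nonlinear
    region-of-interest difference imaging algorithm with parallel level
    sets regularization and a prior-conditioned LSQR solver.
    Detectability of hemorrhage growth is summarised with adjusted
    normalized integrals over a scenario grid of inclusion sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
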