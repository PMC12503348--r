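Package: rhangio
Title: Hybrid Phase-Field Simulation of Tumor-Induced Angiogenesis in
    Retinal Hemangioblastoma
Version: 0.1.0
Authors@R:
    person("Franco", "Devel", email = "devel@example.org", role = c("aut", "cre"))
Description: Simulates the earliest stages of tumor-induced angiogenesis in
    retinal hemangioblastoma with a hybrid continuum/discrete model: a
    Cahn-Hilliard phase field for the capillary network, discrete
    chemotactic tip-cell agents with Notch lateral inhibition, and a
    quasi-steady reaction-diffusion field for the angiogenic factor
    produced by a prescribed slowly growing ellipsoidal tumor.  Includes a
    physical/simulation unit system, synthetic capillary-plexus generation,
    2D-mask to 3D vessel reconstruction via distance transform and
    skeletonization, adaptive implicit time stepping, and a bisection
    estimator of the minimal tumor size capable of triggering sprouting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
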