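Package: hemoflow
Title: Casson Rheology and Desk-Scale Aneurysm Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific hemodynamic analysis of saccular cerebral
    aneurysms at desk scale. Fits the Casson shear-thinning model to
    whole-blood viscosity curves, generates and measures synthetic aneurysm
    dome geometries (height, width, ostium, areas, 5 mm size classification),
    solves pulsatile incompressible generalized-Newtonian flow on a 2D
    channel-and-dome domain with a projection finite-volume scheme, derives
    dome-resolved hemodynamic metrics (shear rate, apparent viscosity, wall
    shear stress, time-averaged WSS), classifies flow patterns
    (simple/complex, diffused/concentrated inflow jet), and compares small
    versus large aneurysm groups with normality-gated two-sample tests. A
    synthetic virtual-patient cohort generator makes the whole pipeline
    reproducible without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    grDevices,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
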