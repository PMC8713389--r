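Package: lvcond
Title: Left Ventricular Volume Estimation from Intracardiac Conductance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and inversion tools for tetrapolar intracardiac
    conductance (bioimpedance) volumetry. Implements three analytical
    calculation methods mapping left-ventricular cavity radius to measured
    conductance - the classical two-point-charge (Wei) model, a charged-plate
    superposition model that mimics field compression at the blood-muscle
    boundary, and a lead-field (reciprocity-consistent) model - together with
    muscle and background tissue compartment corrections, an independent
    numerical-quadrature oracle for the underlying electric-field integrals,
    monotone lookup-table inversion from conductance to radius, cylindrical
    and Wyatt volume models, bench-style fixture generators (glass containers
    and ventricle-shaped phantoms), and Bland-Altman bias / limits-of-agreement
    statistics for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
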