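Package: shootphys
Title: Coupled Leaf Photosynthesis, Stomatal Conductance and Energy Balance
    for Whole-Plant Carbon Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone shoot-physiology engine for functional-structural
    crop simulation: Farquhar-von Caemmerer-Berry C3 and C4 photosynthesis
    with quasi-steady-state mesophyll and bundle-sheath gas concentrations,
    a Ball-Berry-Leuning stomatal conductance model driven by a
    collar-water-potential stress factor, a steady-state leaf energy
    balance solved for leaf temperature, a nested Newton-Raphson solver for
    the coupled leaf system, sun/shade two-fraction canopy scaling,
    nitrogen-limited photosynthetic capacity, day-night starch reserve
    dynamics, and an additive-null statistic for interactions among root
    phene states. Includes a synthetic diurnal weather and terminal-drought
    generator so complete simulations run from code alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
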