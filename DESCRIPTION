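Package: rhodolith
Title: Microscale pH Dynamics, Calcification and Morphometrics of Rhodoliths
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full analysis chain linking coralline algal
    (rhodolith) morphology to thallus-surface chemistry and calcification:
    diffusive boundary layer (DBL) thickness and Fick's-law oxygen fluxes from
    microsensor depth profiles, surface pH anomalies (delta-pH), total
    alkalinity by carbonate-corrected Gran titration, a seawater CO2-system
    solver with calcite saturation state, alkalinity-anomaly calcification and
    chamber metabolic rates, micro-CT style voxel morphometrics with
    mesh-based surface area, and the accompanying regression/ANOVA layer with
    Newman-Keuls letters. Seeded generators emulate every input kind so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    car,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
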