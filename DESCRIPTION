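Package: stomavpd
Title: Stomatal Conductance Responses to Step Changes in Vapor Pressure Deficit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stomatal conductance kinetics around step
    changes in vapor pressure deficit (VPD) measured with gas-exchange systems.
    Computes saturation vapor pressure and VPD, reads per-minute conductance
    logs, masks the instrument-artifact window that follows an abrupt humidity
    change, detects pre- and post-step steady states, and extracts the four
    standard response statistics: wrong-way-response (WWR) amplitude, WWR
    duration, cumulative transpirational water loss during the WWR, and the
    VPD-induced change in steady-state conductance. Includes a seeded
    three-component trajectory simulator (hydropassive overshoot, turgor
    restoration and osmotic closure, steady-state shift) with genotype
    archetypes and an artificial-leaf control, Welch t-test genotype
    comparisons with significance coding, and a porometer-based cultivar
    sensitivity screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
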