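Package: pbrsim
Title: Production Simulation for Flat-Panel Algal Photobioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates long-term biomass and biofuel-feedstock production in
    industrial arrays of vertical flat-panel photobioreactors. Couples a
    clearness-index solar irradiance model with panel-to-panel shading
    geometry, depth-integrated Smith photosynthesis under Beer-Lambert
    attenuation, and an acclimative variable-stoichiometry (Droop-quota)
    model of algal growth with photoacclimative Chl:C dynamics and
    carbon-storage accumulation. Includes harvest/dilution scheduling,
    seasonal temperature forcing of the maximum growth rate, volumetric and
    areal production accounting, and a seedable adaptive random-search
    calibration of unobserved operating parameters against monthly targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
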