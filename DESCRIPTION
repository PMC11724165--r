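Package: fissureflux
Title: Soil CO2 Emission Budgets from Earthquake Surface Fissures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates annual soil CO2 emissions caused by earthquake
    surface fissures on the Qinghai-Tibet Plateau. Implements the full
    estimation chain: chamber flux campaign processing (replicate
    averaging, annualization, group-versus-control ratios), empirical
    magnitude-rupture-length and magnitude-width scaling relations,
    linear fissure healing dynamics with closed-form time-averaged
    sidewall and bottom exposure areas, and conversion of areas to an
    annual carbon emission budget. Includes seeded synthetic generators
    for earthquake catalogs (truncated Gutenberg-Richter magnitudes)
    and hourly chamber flux campaigns, so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
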