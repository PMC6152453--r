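Package: cropgep
Title: Chamber CO2 Fluxes, Daily Gross Ecosystem Production and Spectral
    Models for Croplands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes closed-chamber CO2 concentration traces into net
    ecosystem production (NEP) and ecosystem respiration (Reco) fluxes,
    partitions them with a Lloyd-Taylor temperature response and a
    Michaelis-Menten light response into continuous 30-minute gross
    ecosystem production (GEP), aggregates to daily GEP between sunrise
    and sunset, computes 4-band vegetation indices (NDVI, SAVI, PRI,
    WDRVI/sWDRVI), fits linear spectral models of daily GEP (LAI, VI,
    VI*PARd, VI*LAI), and tests the vegetative/reproductive hysteresis
    of the GEP-VI relationship. Ships a synthetic crop-season generator
    with known ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
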