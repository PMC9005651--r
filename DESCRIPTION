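Package: defoCarbon
Title: Biophysical Carbon Costs of Tropical Deforestation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the additional ("biophysical") aboveground biomass
    carbon losses caused by deforestation-induced regional climate change in
    the tropics. Combines multimodel deforestation-minus-control climate
    deltas with an observationally derived moving-window sensitivity of
    aboveground biomass to mean annual precipitation and temperature, and
    derives regional loss tables, propagated uncertainties, deforestation-
    driven carbon-climate feedback parameters (gamma), and historical
    attribution totals. Includes a synthetic-data generator that emulates the
    statistical structure of the satellite and Earth-system-model inputs so
    the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
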