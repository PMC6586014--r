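Package: stemclim
Title: Stem Water Relations, Phenology and Climate-Growth Analysis for
    Conifers Along Elevation Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking microclimate to tree water relations and radial
    growth of mountain conifers. Decomposes dendrometer stem-radius records
    into irreversible growth (GRO) and reversible tree water deficit (TWD)
    under the zero-growth assumption, fits Gompertz growth phenology, scales
    tissue-heat-balance sap flow to tree-level daily transpiration, builds
    detrended and prewhitened tree-ring chronologies with standard chronology
    statistics and crossdating quality control, estimates bootstrap
    principal-component response functions against monthly climate, and
    classifies regional growth conditions from Thornthwaite climatic water
    deficit under warming scenarios. Includes seeded synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    zoo,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
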