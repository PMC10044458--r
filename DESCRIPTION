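Package: thermozone
Title: Bioclimatic Zoning for Sheep from Kriged Temperature-Humidity Index Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping livestock heat-stress risk from gridded climate
    data. Computes a wind-adjusted temperature-humidity index (THI) per grid
    point and year, characterises its spatial structure by empirical
    semivariograms and weighted least-squares fits of spherical, exponential
    and Gaussian models, interpolates annual THI surfaces by ordinary kriging
    with leave-one-out cross-validation for model selection, and classifies
    territory into per-breed sheep suitability zones against published
    critical THI limits. A stationary Gaussian random-field simulator with
    prescribed nugget, sill and range generates synthetic multi-year climate
    series over a partitioned study region so the whole pipeline runs and is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
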