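Package: aphidscape
Title: Landscape Floral-Resource Maps and Two-Step Models for Aphid Predators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conservation biological control at the
    landscape scale. Builds floral-resource maps from field flower surveys
    (assessment cubes in grasslands and crops, woody transects with
    calibration cubes), summarises land cover within circular landscape
    sectors, pools phytometer surveys of aphid predators and aphid
    population growth, and fits the two-step (hurdle) regression framework
    for zero-inflated predator counts with AICc, generalized R-squared,
    standardized coefficients, variance-inflation screening and permutation
    tests. Includes a synthetic-study generator with known ground truth for
    power, type-I-error and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
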