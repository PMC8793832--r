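Package: nutriflow
Title: Global Food-System Nutrient Availability Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-flow accounting of global food production into
    population-level nutrient availability. Fits a linear-trend baseline to
    food-balance-sheet commodity time series, subdivides commodities into
    food types with processing yields and inedible fractions, deducts
    regional in-home waste, converts edible mass into 29 nutrients via a
    food composition table, applies bioavailability coefficients to protein
    and seven indispensable amino acids, and compares per-capita supply
    against demographically weighted nutrient reference targets. Includes
    contribution and nutrient-density rankings, DIAAS protein-quality
    scoring, production and waste scenario analysis, and a synthetic-data
    generator with an independent ground-truth oracle so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
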