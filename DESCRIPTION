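Package: deltafood
Title: Mass-Balance Modelling of Global Food-System Nutrient Adequacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scenario engine for global food-system nutrition. Converts
    food-group production into per-capita daily nutrient availability via a
    mass-balance cascade (item disaggregation from commodity balance sheets,
    deduction of animal feed, supply-chain losses, nonfood uses, inedible
    portions and in-home waste), weights protein and indispensable amino
    acids by digestibility, and compares supply against demographically
    weighted dietary reference values to report nutrient gaps, excesses and
    the nutrients embodied in wasted food. Includes scenario transformations
    (uniform scaling, group removal with compensation or reallocation, waste
    multipliers, vegetarian/vegan target switching for iron and zinc), a
    synthetic miniature-world generator, and an independent brute-force
    oracle for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
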