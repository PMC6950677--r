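Package: foplabel
Title: Front-of-Package Claims and Nutrient Profiling of Packaged Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify packaged foods and beverages as "high in"
    critical nutrients under a modified PAHO nutrient profile model with
    the Chilean-law eligibility criterion, to screen Portuguese ingredient
    lists for added sugar, salt, fat and nonnutritive sweeteners, to
    estimate free sugars from declared total sugars by category fractions,
    to classify front-of-package claims under an INFORMAS-based taxonomy,
    and to reproduce the associated prevalence and reliability analyses on
    synthetic packaged-food-label data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
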