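Package: nutrivalid
Title: Validation of Dietary Assessment Tools Against Doubly Labelled Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for validating dietary self-report tools
    (image-based apps, 24-hour recalls) against the doubly labelled water
    (DLW) reference method. Implements two-point DLW isotope kinetics
    (elimination rates, dilution spaces, CO2 production and the Weir
    equation), energy-requirement prediction (Devine ideal body weight,
    adjusted body weight, Mifflin-St Jeor and Harris-Benedict equations)
    with three physical-activity-level variants, Goldberg cut-off
    misreporting classification with configurable variability factors,
    method-comparison statistics (Bland-Altman limits of agreement with
    explicit divisor conventions, Pearson association, normality-gated
    paired tests, two-way random-effects intraclass correlation), and a
    nine-facet validity scorecard. A seeded synthetic-cohort generator
    emulates the data structure of a free-living validation study so every
    stage can be exercised and tested without access to individual data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
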