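Package: urbanpoverty
Title: Household-Survey Poverty Measurement and Evaluation for Cities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and characterising the urban poor from
    DHS/MICS-style household survey microdata. Implements seven household-level
    poverty classifiers (four relative wealth-index cut-offs, a predicted-income
    poverty line, a multidimensional socioeconomic deprivation score, and the
    UN-Habitat slum definition), a three-criterion procedure for selecting the
    preferred classifier across cities, five household welfare outcome
    indicators, a city performance classification based on prevalence and
    poor-rich gaps, and correlations of city results with macro-level human
    development indices. Ships a synthetic multi-city survey generator so the
    full pipeline is testable without restricted-access survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
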