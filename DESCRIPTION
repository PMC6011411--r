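Package: ethnomarket
Title: Quantitative Analysis of Medicinal-Plant Market Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ethnobotanical market
    surveys recorded as long-format use reports (species sold in a market for
    an ailment within an illness category). Implements taxon and use-category
    summaries, the logarithmic informant consensus (LIC) index with markets as
    occurrences, market-by-item incidence matrices with shared/unique
    decompositions and Euclidean market distances, principal coordinates
    ordination, permutation tests of market grouping (pseudo-F) and of
    size association (Mantel-style), and a synthetic survey generator for
    calibration and power studies. Ships a structured transcription of a
    24-market medicinal plant inventory from Bogota, Colombia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
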