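Package: betanull
Title: Bidimensional Null-Model Analysis of Beta-Diversity Partitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions multiple-site beta-diversity into its spatial turnover
    and nestedness components (Sorensen/Simpson family), measures the deviation
    of each component from null expectation across a complete bidimensional
    null space of marginal-total constraints (from the fixed-fixed to the
    equiprobable ensemble, with matrix fill always conserved), and compares
    deviations across temperature-defined site groups with rank-sum tests and
    Holm correction. Includes a synthetic metacommunity generator emulating an
    elevational-gradient incidence data set, so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
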