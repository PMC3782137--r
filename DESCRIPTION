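Package: ethnoquant
Title: Quantitative Analysis of Ethnomedicinal Use-Report Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative side of ethnomedicinal field
    surveys: a validated tabular data model for disorder-by-species use
    reports, the informant consensus factor (ICF) and fidelity level (FL)
    indices with exact display rounding, summary tabulations, bipartite
    disorder-species network analysis with one-mode projections and
    GraphML export, and a Dirichlet-multinomial simulator for synthetic
    surveys with a tunable consensus level. Ships a complete worked
    dataset: a 121-record survey of ethnomedicinal liver-disorder
    treatments from southern Korea.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
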