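Package: relflux
Title: Relational Models from Dyadic Action Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Formal model of dyadic social relationships as sets of
    elementary interactions built from directed social actions ("action
    fluxes"), with exact enumeration of the relationship space for N
    actions, decomposition of any relationship into six exhaustive
    categories mapped to relational models theory (Equality Matching,
    Null, Market Pricing, Authority Ranking, Communal Sharing, and
    Unilateral/Asocial), a classifier that detects these categories in
    time-stamped dyadic interaction event logs using an alternation
    statistic with a permutation null, social-unit detection from
    weighted interaction graphs, and a seeded synthetic event-log
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
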