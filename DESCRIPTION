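Package: stpra
Title: Sociotechnical Probabilistic Risk Assessment with Fault Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fault tree analysis for sociotechnical probabilistic risk
    assessment (ST-PRA) of adverse events in health care, built around a
    reconstruction of a fall-risk model for psychiatric seclusion rooms.
    Provides a fault-tree data model with JSON, YAML and Open-PSA MEF XML
    serialization, aggregation of multi-source (literature and expert)
    probability estimates into low/average/high point estimates, minimal
    cut set enumeration by top-down MOCUS expansion, exact top-event
    probabilities via Shannon factoring of repeated events plus rare-event
    and min-cut-upper-bound approximations and a seeded Monte Carlo
    oracle, Birnbaum/criticality/Fussell-Vesely importance measures,
    low/average/high and leave-one-out sensitivity analyses, and a seeded
    generator of random coherent fault trees for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
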