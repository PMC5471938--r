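Package: lbdiscovery
Title: Hidden-Knowledge Generation and Filtering for Literature-Based
    Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Literature-based discovery over concept-relation graphs built
    from extracted subject-predicate-object predications. Implements
    hidden-knowledge generation at arbitrary linking depth via binarized
    adjacency-matrix powers (the A-B-C model and its multi-step
    generalization), four filtering strategies (source-asserted synonym
    merging, semantic-type inclusion/exclusion, automatic common-linking-term
    stoplists, and degree-based connection breaking), and two evaluation
    protocols (replication of known discoveries with direct-document removal,
    and timeslicing with precision/recall/F-measure). Ships a fully seeded
    synthetic predication-corpus generator with plantable discovery chains so
    every component is testable without licensed predication databases, plus
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
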