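Package: rxnpath
Title: Reaction-Path Prediction via Molecular Graph Enumeration and
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts chemical reaction paths by combinatorial enumeration
    of reaction intermediates as atom-connectivity matrices, chemical
    plausibility screening (bond orders, valence, formal charge, rings,
    energy tolerance), construction of a reaction network weighted by the
    minimum number of bond changes (chemical distance, minimized over
    element-preserving atom mappings), and extraction of the minimal
    subnetwork of shortest reactant-to-product paths with Dijkstra/Yen
    sampling, path ranking and pluggable energy-based filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
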