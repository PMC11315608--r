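Package: communet
Title: Reduced Interaction Networks from Community Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces compartmentalized community genome-scale metabolic
    models (SBML Level 3 with FBC, PyCoMo-style member prefixes and a
    shared external compartment) to bipartite organism/exchange-metabolite
    interaction networks, lays them out on four concentric circles,
    contextualizes edges with flux balance analysis fluxes or flux
    variability analysis ranges, isolates cross-feeding interactions,
    computes bidirectionality statistics, and exports GraphML, Cytoscape
    JSON and SVG/PNG figures. Includes a seeded generator of synthetic toy
    community models with ground-truth records for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
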