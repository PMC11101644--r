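Package: emtmap
Title: Disease-Map Curation, Boolean Dynamics and Hub Analysis for TGFbeta-Induced EMT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with literature-curated molecular interaction
    maps of epithelial-mesenchymal transition (EMT) in metastatic breast
    cancer and, more generally, with signed directed regulatory maps. The
    package reads CellDesigner-dialect SBML and SIF-like edge tables into a
    common map representation, translates maps into Boolean logical models
    following the CaSQ convention, simulates them under synchronous and
    asynchronous update schemes with ensemble activity-level readouts,
    classifies epithelial/mesenchymal/hybrid phenotypes from marker node
    sets, computes a battery of network-topology metrics together with
    maximal clique centrality (MCC) hub rankings, and generates seeded
    random regulatory maps with injectable feedback motifs, including a
    curated EMT-core fixture. SBML-qual import/export is supported for
    binary logical models.
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
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
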