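Package: skullnet
Title: Anatomical Network Analysis of Skull Bone-Articulation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models vertebrate skulls as networks of bones (nodes) and
    sutural articulations (links) and analyses their topology. Provides
    constructors and validators for skull networks, bone-fusion editing,
    the eight whole-skull topological variables used in anatomical network
    analysis (node and link counts, density, clustering, path length,
    heterogeneity, assortativity, parcellation), node-based informed
    module detection built on spinglass community search with
    hypergeometric merging of redundant candidates, a morphospace stage
    (principal component analysis of the topological variables plus
    PERMANOVA group tests), and a synthetic generator of bilaterally
    symmetric skull-like networks with simulated bone-fusion trajectories
    for testing the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
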