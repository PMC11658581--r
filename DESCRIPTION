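Package: lesionconn
Title: Differential Lesion Connectomics and Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the structural and dynamic consequences of
    focal brain lesions on weighted, directed, bilateral connectomes. Provides
    a connectome data model with readers and writers for edge-list CSV,
    GraphML and JSON; a synthetic-connectome generator with controllable
    reciprocity, hub structure and hemispheric mirroring; differential
    connectomics reports comparing control and lesioned networks; global and
    local graph metrics (reciprocity, path length, clustering, transitivity,
    small-worldness, knotty-centrality, average local-parameter ranks);
    Erdos-Renyi and degree-preserving null-model ensembles with permutation
    tests; connectivity-matching and generalized topological-overlap
    similarity indices; coupled FitzHugh-Nagumo, Wilson-Cowan and
    Mimura-Murray node dynamics with spike detection, coactivation and
    Kuramoto synchrony summaries; and a leaky integrate-and-fire population
    simulator with interspike-interval variability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
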