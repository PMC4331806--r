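Package: ISHC
Title: Synchronization-Based Hierarchical Clustering of Protein
    Interaction Networks with Firefly Optimization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks by coupling a spectral embedding of the interaction graph with
    synchronization-based hierarchical clustering (SHC). Proteins are mapped
    to three-dimensional coordinates via the top eigenvectors of a
    degree-normalized edge-similarity matrix, then treated as coupled phase
    oscillators: objects within a neighborhood radius epsilon attract each
    other until epsilon-neighborhood closures form, and each closure becomes
    a cluster. The critical radius epsilon is tuned automatically by a
    firefly-algorithm search against a weighted modularity objective, with a
    hierarchical grid search available as a baseline. Includes
    precision/recall/f-measure evaluation against reference complex sets and
    a planted-partition generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: Network, Clustering, GraphAndNetwork, Proteomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
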