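Package: sisdta
Title: Drug-Target Binding Affinity Prediction with Structure-Inclusive
    Similarity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression of drug-target binding affinities with a directed
    graph convolutional network built on structure-inclusive similarity
    (SIS), an asymmetric containment similarity over extended-connectivity
    fingerprint (ECFP) substructure sets. Provides circular substructure
    enumeration from SMILES, SIS/Tanimoto/Jaccard/Euclidean and normalized
    Smith-Waterman similarity matrices, directed relationship-graph
    construction by thresholding with k-nearest-neighbour backfill,
    weighted graph convolution with multi-view feature fusion and an
    autoencoder reconstruction objective, the standard affinity-regression
    metrics (MSE, RMSE, concordance index, rm2 index, Spearman), seeded
    synthetic data generators, and readers/writers for the common dataset
    layout (SMILES/sequence maps, GO annotations, embedding tables,
    affinity matrices, fold indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
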