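Package: histocell
Title: Hierarchical Cell and Tissue Phenotyping for H&E Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A hierarchical pipeline for quantifying cells and tissue
    microstructures in hematoxylin-and-eosin stained whole-slide images.
    Slides are tiled into overlapping patches at a standard physical
    resolution, nuclei are localised and deduplicated, nucleus-centred
    crops are classified into placental cell types with penultimate-layer
    embeddings, a whole-slide cell graph is built from the intersection of
    k-nearest-neighbour and Delaunay edges, and an inductive
    message-passing graph neural network assigns each cell a tissue
    microstructure class.  Downstream utilities compute per-slide
    proportions, occupied tissue area and per-square-millimetre densities,
    compare groups with Welch's t-test under Bonferroni correction, and
    analyse inter-rater agreement with Cohen's kappa.  Synthetic slide and
    cell-graph generators provide self-contained fixtures for training and
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    Matrix,
    igraph,
    nnet,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
Config/testthat/edition: 3
RoxygenNote: 7.3.3
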