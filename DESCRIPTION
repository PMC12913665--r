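Package: gplnd
Title: Graph-Pruned Detection of Lymph Node Metastases in Histology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end graph-based analysis of histopathology image tiles for
    lymph node metastasis detection. Tiles are partitioned into SLIC
    superpixels and turned into attributed graphs; a dynamic graph convolution
    autoencoder with node-attribute attention segments metastatic regions; a
    comprehensive gradual pruning scheme jointly sparsifies model weights,
    graph edges and feature dimensions with magnitude pruning and
    gradient-based regrowth; Hessian-weighted locally linear embedding reduces
    segmentation-derived descriptors; and a graph neural network classifier
    with the same pruning regulariser labels tiles as metastatic or not. A
    seeded generator of H&E-like synthetic tiles with pixel-exact ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
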