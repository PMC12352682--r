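Package: resolvST
Title: Super-Resolution of Spot-Based Spatial Transcriptomics by Hybrid
    Convolutional, Attention and Graph Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Doubles the spatial resolution of spot-based spatial
    transcriptomics (classic square-lattice ST and staggered Visium
    arrays) by predicting gene expression at unmeasured lattice
    positions. A hybrid network - a convolutional front-end, a vision
    transformer with sinusoidal positional encoding, and a Gaussian-kernel
    k-nearest-neighbour graph module embedded in each transformer
    block - is trained self-supervised on down-sampled/original grid
    pairs with a tissue-masked multi-channel mean squared error, and
    emits four sub-pixel channels that interleave into a 2x grid.
    Includes the geometric down-sampling evaluation protocol, classical
    interpolation baselines (nearest, bilinear, bicubic, edge-directed),
    gene-wise Pearson correlation and clustering metrics (silhouette,
    Davies-Bouldin), readers and writers for common spot-table formats,
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
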