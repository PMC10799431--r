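Package: velogcn
Title: Cell-Specific RNA Velocity from Graph Convolutional Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates cell-specific and gene-specific RNA splicing kinetics
    (transcription, splicing and degradation rates) and RNA velocity from
    spliced and unspliced single-cell count matrices. A graph convolutional
    network over the cell k-nearest-neighbour graph predicts per-cell kinetic
    rates and is trained with a self-supervised continuity objective that
    extrapolates each cell towards the observed expression of candidate
    future (and past) neighbour cells, with a Pearson-correlation term to fix
    the velocity direction. Includes a splicing-kinetics ODE simulator with
    time-dependent degradation rates and multi-regime genes, velocity
    consistency / continuity / direction metrics, velocity-graph construction
    with confidence-based gene filtering, projection of velocities onto 2-D
    embeddings, and driver-gene ranking by pseudotime correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: RNASeq, SingleCell, GeneExpression, Software
RoxygenNote: 7.3.3
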