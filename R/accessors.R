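#' Accessors for VeloSet layers and annotation
#'
#' @param x a \linkS4class{VeloSet} (or \linkS4class{KineticRates},
#'   \linkS4class{VelocityEstimate}, \linkS4class{NeighborGraph},
#'   \linkS4class{VelocityGraph} where noted).
#' @return the requested matrix or vector; layer matrices are genes x cells.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spliced", function(x) standardGeneric("spliced"))
#' @rdname accessors
#' @export
setMethod("spliced", "VeloSet", function(x) assay(x, "spliced"))

#' @rdname accessors
#' @export
setGeneric("unspliced", function(x) standardGeneric("unspliced"))
#' @rdname accessors
#' @export
setMethod("unspliced", "VeloSet", function(x) assay(x, "unspliced"))

#' @rdname accessors
#' @export
setGeneric("splicedSmooth", function(x) standardGeneric("splicedSmooth"))
#' @rdname accessors
#' @export
setMethod("splicedSmooth", "VeloSet", function(x) {
    if (!"spliced_smooth" %in% assayNames(x))
        stop("no smoothed layers: run smoothByNeighbors() (or preprocess()) first")
    assay(x, "spliced_smooth")
})

#' @rdname accessors
#' @export
setGeneric("unsplicedSmooth", function(x) standardGeneric("unsplicedSmooth"))
#' @rdname accessors
#' @export
setMethod("unsplicedSmooth", "VeloSet", function(x) {
    if (!"unspliced_smooth" %in% assayNames(x))
        stop("no smoothed layers: run smoothByNeighbors() (or preprocess()) first")
    assay(x, "unspliced_smooth")
})

#' @rdname accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))
#' @rdname accessors
#' @export
setMethod("cellType", "VeloSet", function(x) colData(x)$cell_type)

#' @rdname accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))
#' @rdname accessors
#' @export
setMethod("pseudotime", "VeloSet", function(x) colData(x)$pseudotime)

#' @rdname accessors
#' @export
setGeneric("neighborGraph", function(x) standardGeneric("neighborGraph"))
#' @rdname accessors
#' @export
setMethod("neighborGraph", "VeloSet", function(x) metadata(x)$neighbor_graph)

#' @rdname accessors
#' @export
setGeneric("rateAlpha", function(x) standardGeneric("rateAlpha"))
#' @rdname accessors
#' @export
setMethod("rateAlpha", "KineticRates", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("rateBeta", function(x) standardGeneric("rateBeta"))
#' @rdname accessors
#' @export
setMethod("rateBeta", "KineticRates", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("rateGamma", function(x) standardGeneric("rateGamma"))
#' @rdname accessors
#' @export
setMethod("rateGamma", "KineticRates", function(x) x@gamma)

#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))
#' @rdname accessors
#' @export
setMethod("velocity", "VelocityEstimate", function(x) x@v)
#' @rdname accessors
#' @export
setMethod("velocity", "VeloSet", function(x) {
    if (!"velocity" %in% assayNames(x))
        stop("no 'velocity' assay present")
    assay(x, "velocity")
})

#' @rdname accessors
#' @export
setGeneric("velocityUnspliced", function(x) standardGeneric("velocityUnspliced"))
#' @rdname accessors
#' @export
setMethod("velocityUnspliced", "VelocityEstimate", function(x) x@vUns)

#' @rdname accessors
#' @export
setGeneric("knnIndex", function(x) standardGeneric("knnIndex"))
#' @rdname accessors
#' @export
setMethod("knnIndex", "NeighborGraph", function(x) x@index)

#' @rdname accessors
#' @export
setGeneric("knnDistance", function(x) standardGeneric("knnDistance"))
#' @rdname accessors
#' @export
setMethod("knnDistance", "NeighborGraph", function(x) x@distance)

#' @rdname accessors
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))
#' @rdname accessors
#' @export
setMethod("graphWeights", "VelocityGraph", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "VelocityGraph", function(x) x@transition)

#' @rdname accessors
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))
#' @rdname accessors
#' @export
setMethod("genesUsed", "VelocityGraph", function(x) x@genesUsed)

#' Ground truth of a simulated dataset
#'
#' Returns the stored simulation truth (pseudotime, noise-free velocity,
#' per-gene kinetics, lineage, seed) of a dataset produced by
#' \code{\link{simulatePopulation}} or \code{\link{simulateTwoRegimeGene}}.
#'
#' @param x a simulated \linkS4class{VeloSet}.
#' @return a list with elements \code{pseudotime}, \code{true_velocity}
#'   (genes x cells), \code{kinetics} (data.frame), \code{lineage},
#'   \code{seed}; NULL for non-simulated data.
#' @export
simulationTruth <- function(x) metadata(x)$simulation_truth

#' Symmetrized adjacency of a neighbour graph
#'
#' Directed kNN edges are kept if present in either direction (the symmetric
#' normalization of the graph convolution presumes an undirected graph).
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param self add self loops.
#' @return a sparse 0/1 \code{dgCMatrix}.
#' @export
symmetricAdjacency <- function(graph, self = FALSE) {
    n <- nrow(graph@index)
    if (graph@k == 0L) {
        a <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                          dims = c(n, n))
    } else {
        i <- rep(seq_len(n), graph@k)
        j <- as.vector(graph@index)
        a <- sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
        a <- a + Matrix::t(a)
    }
    if (self) a <- a + Diagonal(n)
    a@x[] <- 1
    a
}

#' Symmetrically normalized adjacency with self loops
#'
#' Computes D^{-1/2} (A + I) D^{-1/2} on the symmetrized neighbour graph,
#' the propagation operator of the graph convolution.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @return a sparse symmetric matrix.
#' @export
normalizedAdjacency <- function(graph) {
    a <- symmetricAdjacency(graph, self = TRUE)
    d <- Matrix::rowSums(a)
    dinv <- Diagonal(x = 1 / sqrt(d))
    dinv %*% a %*% dinv
}

#' Row-stochastic neighbour-smoothing operator
#'
#' Each row averages a cell and its k nearest neighbours (weight 1/(k+1)).
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @return a sparse row-stochastic matrix.
#' @export
smoothingMatrix <- function(graph) {
    n <- nrow(graph@index)
    if (graph@k == 0L) return(Diagonal(n))
    i <- c(seq_len(n), rep(seq_len(n), graph@k))
    j <- c(seq_len(n), as.vector(graph@index))
    sparseMatrix(i = i, j = j, x = 1 / (graph@k + 1), dims = c(n, n))
}
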