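#' @import methods
#' @import S4Vectors
#' @import SummarizedExperiment
#' @import SingleCellExperiment
#' @importFrom Matrix Matrix sparseMatrix Diagonal readMM writeMM nnzero
NULL

#' VeloSet: spliced/unspliced expression container
#'
#' A \linkS4class{SingleCellExperiment} subclass holding the two count layers
#' RNA velocity estimation needs: \code{"spliced"} (mature mRNA) and
#' \code{"unspliced"} (intronic pre-mRNA), genes in rows and cells in columns.
#' Optional per-cell annotation lives in \code{colData} (columns
#' \code{cell_type}, \code{pseudotime}, \code{lineage}), low-dimensional
#' coordinates in \code{reducedDims} (\code{"PCA"}, \code{"EMBED"}).
#' Preprocessing adds assays \code{"spliced_smooth"} / \code{"unspliced_smooth"}
#' and records the neighbour graph in \code{metadata(x)$neighbor_graph}.
#'
#' @export
setClass("VeloSet", contains = "SingleCellExperiment")

setValidity("VeloSet", function(object) {
    an <- assayNames(object)
    if (!all(c("spliced", "unspliced") %in% an))
        return("assays 'spliced' and 'unspliced' are required")
    s <- assay(object, "spliced")
    u <- assay(object, "unspliced")
    if (!identical(dim(s), dim(u)))
        return("'spliced' and 'unspliced' must have identical shape")
    if (min(s) < 0 || min(u) < 0)
        return("count layers must be nonnegative")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        return("gene names must be present and unique")
    # NOTE: reducedDims consistency (e.g. the EMBED row count) is enforced by
    # the reducedDim<- setter; querying reducedDims from inside a validity
    # method would re-trigger validation and recurse.
    TRUE
})

#' Construct a VeloSet
#'
#' @param spliced,unspliced numeric matrices, genes x cells, nonnegative and of
#'   identical shape. Dimnames are used as gene names / cell ids; defaults are
#'   generated when absent.
#' @param cell_type optional factor/character of cell-type labels per cell.
#' @param pseudotime optional numeric vector per cell.
#' @param lineage optional factor/character per cell.
#' @param embedding optional cells x 2 coordinate matrix (stored as
#'   \code{reducedDim "EMBED"}).
#' @param metadata list of extra metadata.
#' @return A \linkS4class{VeloSet}.
#' @examples
#' vs <- VeloSet(spliced = matrix(1:6, 3), unspliced = matrix(0:5, 3))
#' vs
#' @export
VeloSet <- function(spliced, unspliced, cell_type = NULL, pseudotime = NULL,
                    lineage = NULL, embedding = NULL, metadata = list()) {
    spliced <- as.matrix(spliced)
    unspliced <- as.matrix(unspliced)
    if (!identical(dim(spliced), dim(unspliced)))
        stop("'spliced' and 'unspliced' must have identical shape")
    if (is.null(rownames(spliced)))
        rownames(spliced) <- sprintf("gene_%d", seq_len(nrow(spliced)))
    if (is.null(colnames(spliced)))
        colnames(spliced) <- sprintf("cell_%d", seq_len(ncol(spliced)))
    dimnames(unspliced) <- dimnames(spliced)
    cd <- DataFrame(row.names = colnames(spliced))
    if (!is.null(cell_type)) cd$cell_type <- cell_type
    if (!is.null(pseudotime)) cd$pseudotime <- as.numeric(pseudotime)
    if (!is.null(lineage)) cd$lineage <- lineage
    sce <- SingleCellExperiment(
        assays = list(spliced = spliced, unspliced = unspliced),
        colData = cd, metadata = metadata)
    if (!is.null(embedding)) {
        embedding <- as.matrix(embedding)
        rownames(embedding) <- colnames(spliced)
        reducedDim(sce, "EMBED") <- embedding
    }
    new("VeloSet", sce)
}

#' Nearest-neighbour graph over cells
#'
#' Row i lists the \code{k} nearest other cells of cell i (1-based indices),
#' nearest first, self excluded; ties broken towards the lower cell index.
#'
#' @slot index integer matrix N x k of neighbour positions.
#' @slot distance numeric matrix N x k, nondecreasing along each row.
#' @slot k integer neighbourhood size.
#' @slot metric distance label.
#' @export
setClass("NeighborGraph",
    representation(index = "matrix", distance = "matrix",
                   k = "integer", metric = "character"))

setValidity("NeighborGraph", function(object) {
    n <- nrow(object@index)
    if (!identical(dim(object@index), dim(object@distance)))
        return("index and distance shape differ")
    if (ncol(object@index) != object@k)
        return("k does not match index columns")
    if (object@k > 0) {
        if (any(object@index < 1L) || any(object@index > n))
            return("neighbour indices out of range")
        if (any(object@index == row(object@index)))
            return("self-neighbours are not allowed")
        dd <- object@distance
        if (ncol(dd) > 1 && any(dd[, -1, drop = FALSE] -
                                dd[, -ncol(dd), drop = FALSE] < -1e-12))
            return("distances must be nondecreasing along rows")
    }
    TRUE
})

#' Per-cell, per-gene kinetic rates
#'
#' Transcription (alpha), splicing (beta) and degradation (gamma) rates of the
#' splicing ODE, estimated per cell and gene; genes x cells, nonnegative.
#' \code{alpha} is NULL unless the model was built with an alpha head.
#'
#' @slot alpha NULL or genes x cells matrix.
#' @slot beta,gamma genes x cells matrices.
#' @export
setClass("KineticRates",
    representation(alpha = "ANY", beta = "matrix", gamma = "matrix"))

setValidity("KineticRates", function(object) {
    if (!identical(dim(object@beta), dim(object@gamma)))
        return("beta and gamma shapes differ")
    if (min(object@beta) < 0 || min(object@gamma) < 0)
        return("rates must be nonnegative")
    if (!is.null(object@alpha)) {
        if (!identical(dim(object@alpha), dim(object@beta)))
            return("alpha shape differs from beta")
        if (min(object@alpha) < 0) return("rates must be nonnegative")
    }
    TRUE
})

#' Per-cell, per-gene velocity estimates
#'
#' \code{v} is the estimated time derivative of spliced abundance
#' (genes x cells); \code{vUns}, when present, the derivative of unspliced
#' abundance.
#'
#' @slot v genes x cells matrix.
#' @slot vUns NULL or genes x cells matrix.
#' @export
setClass("VelocityEstimate", representation(v = "matrix", vUns = "ANY"))

setValidity("VelocityEstimate", function(object) {
    if (!all(is.finite(object@v))) return("velocities must be finite")
    if (!is.null(object@vUns) && !identical(dim(object@vUns), dim(object@v)))
        return("vUns shape differs from v")
    TRUE
})

#' Candidate target/source cell distribution
#'
#' For each cell, a uniform probability 1/Z over the neighbour candidates whose
#' displacement has positive cosine with the (signed) velocity, zero elsewhere.
#' Z counts the positive-cosine candidates; cells with Z = 0 have an all-zero
#' row and are flagged in \code{empty}.
#'
#' @slot candidates integer matrix N x k of candidate cell indices.
#' @slot prob numeric matrix N x k, rows valued in {0, 1/Z}.
#' @slot z integer vector of per-cell normalizer counts.
#' @slot direction "forward" or "backward".
#' @export
setClass("TargetDistribution",
    representation(candidates = "matrix", prob = "matrix",
                   z = "integer", direction = "character"))

setValidity("TargetDistribution", function(object) {
    if (!identical(dim(object@candidates), dim(object@prob)))
        return("candidates and prob shape differ")
    rs <- rowSums(object@prob)
    ok <- abs(rs - 1) < 1e-8 | rs == 0
    if (!all(ok)) return("probability rows must sum to 1 or be all zero")
    if (!object@direction %in% c("forward", "backward"))
        return("direction must be 'forward' or 'backward'")
    TRUE
})

#' Graph convolutional rate model
#'
#' Trainable state of the rate-predicting network: the graph convolution
#' weights, the fully connected output head mapping the last hidden layer to
#' rate blocks, and the symmetrically normalized adjacency (with self loops)
#' it propagates over.
#'
#' @slot weights list of layer weight matrices (\code{W1}, \code{W2}, ...,
#'   \code{W_head}, \code{b_head}).
#' @slot normAdj sparse normalized adjacency.
#' @slot config list of architecture settings.
#' @export
setClass("GcnModel",
    representation(weights = "list", normAdj = "ANY", config = "list"))

#' Velocity graph
#'
#' Sparse cell-to-cell weights w_ij = cosine(v_i, s_j - s_i) on neighbour
#' edges, plus the Gaussian-normalized row-stochastic transition matrix.
#'
#' @slot weights sparse N x N matrix of cosine weights.
#' @slot transition sparse N x N row-stochastic matrix.
#' @slot genesUsed integer indices of genes used after confidence filtering.
#' @export
setClass("VelocityGraph",
    representation(weights = "ANY", transition = "ANY",
                   genesUsed = "integer"))

setMethod("show", "VeloSet", function(object) {
    callNextMethod()
    gr <- metadata(object)$neighbor_graph
    if (!is.null(gr))
        cat(sprintf("neighbor graph: k=%d (%s)\n", gr@k, gr@metric))
})

setMethod("show", "NeighborGraph", function(object) {
    cat(sprintf("NeighborGraph: %d cells, k=%d, metric=%s\n",
                nrow(object@index), object@k, object@metric))
})

setMethod("show", "KineticRates", function(object) {
    cat(sprintf("KineticRates: %d genes x %d cells (%s)\n",
                nrow(object@beta), ncol(object@beta),
                if (is.null(object@alpha)) "beta, gamma"
                else "alpha, beta, gamma"))
})

setMethod("show", "VelocityEstimate", function(object) {
    cat(sprintf("VelocityEstimate: %d genes x %d cells%s\n",
                nrow(object@v), ncol(object@v),
                if (is.null(object@vUns)) "" else " (+ unspliced derivative)"))
})

setMethod("show", "TargetDistribution", function(object) {
    cat(sprintf("TargetDistribution (%s): %d cells, %d candidates, %d empty\n",
                object@direction, nrow(object@prob), ncol(object@prob),
                sum(object@z == 0L)))
})

setMethod("show", "VelocityGraph", function(object) {
    cat(sprintf("VelocityGraph: %d cells, %d edges, %d genes used\n",
                nrow(object@weights), Matrix::nnzero(object@weights),
                length(object@genesUsed)))
})
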