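#' Preprocessing configuration
#'
#' Bundles the knobs of the standard preparation chain
#' (normalize -> highly variable genes -> PCA -> kNN -> neighbour smoothing).
#'
#' @param n_top_genes number of highly variable genes to keep (default 2000).
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbourhood size of the cell kNN graph (default 30).
#' @param normalize_target per-cell spliced total after normalization;
#'   \code{"median"} (default) uses the median spliced library size, a number
#'   fixes the total, \code{"none"} skips depth normalization (appropriate
#'   for simulated abundances, which carry no sequencing-depth variation).
#' @param log_for_pca use log1p-transformed spliced counts for PCA.
#' @return a list of class \code{preprocess_config}.
#' @export
preprocessConfig <- function(n_top_genes = 2000L, n_pcs = 30L,
                             k_neighbors = 30L, normalize_target = "median",
                             log_for_pca = TRUE) {
    stopifnot(n_top_genes >= 1, n_pcs >= 1, k_neighbors >= 1)
    structure(list(n_top_genes = as.integer(n_top_genes),
                   n_pcs = as.integer(n_pcs),
                   k_neighbors = as.integer(k_neighbors),
                   normalize_target = normalize_target,
                   log_for_pca = isTRUE(log_for_pca)),
              class = "preprocess_config")
}

#' Library-size normalization of both count layers
#'
#' Scales each cell so its spliced total equals the target (median spliced
#' library size by default) and applies the same per-cell factor to the
#' unspliced layer, preserving the unspliced/spliced ratio velocity depends
#' on. Cells with zero spliced total are dropped with a warning. The
#' pre-normalization layers are kept as assays \code{"raw_spliced"} /
#' \code{"raw_unspliced"}.
#'
#' @param x a \linkS4class{VeloSet}.
#' @param target numeric target total, or \code{"median"}.
#' @return a normalized \linkS4class{VeloSet}.
#' @export
normalizeCounts <- function(x, target = "median") {
    s <- as.matrix(spliced(x))
    u <- as.matrix(unspliced(x))
    tot <- colSums(s)
    keep <- tot > 0
    if (!all(keep)) {
        warning(sprintf("dropping %d cell(s) with zero spliced total", sum(!keep)))
        x <- x[, keep]
        s <- s[, keep, drop = FALSE]
        u <- u[, keep, drop = FALSE]
        tot <- tot[keep]
    }
    if (identical(target, "none")) {
        tgt <- NA_real_
        f <- rep(1, length(tot))
    } else {
        tgt <- if (identical(target, "median")) stats::median(tot)
               else as.numeric(target)
        f <- tgt / tot
    }
    assay(x, "raw_spliced") <- s
    assay(x, "raw_unspliced") <- u
    assay(x, "spliced") <- sweep(s, 2, f, "*")
    assay(x, "unspliced") <- sweep(u, 2, f, "*")
    metadata(x)$size_factors <- 1 / f
    metadata(x)$normalize_target <- tgt
    x
}

# binned dispersion of log1p spliced counts: var/mean per gene, z-scored
# within up to 20 equal-frequency mean bins (capped so bins average at least
# five genes; degenerate bins would zero every score)
.dispersion_stat <- function(s, n_bins = 20L) {
    ls <- log1p(s)
    m <- rowMeans(ls)
    v <- apply(ls, 1, stats::var)
    disp <- ifelse(m > 0, v / m, 0)
    n_bins <- max(1L, min(n_bins, nrow(s) %/% 5L, length(unique(m))))
    br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(m, breaks = br, include.lowest = TRUE)
    z <- disp
    for (b in levels(bin)) {
        idx <- which(bin == b)
        mu <- mean(disp[idx])
        sd <- stats::sd(disp[idx])
        z[idx] <- if (is.na(sd) || sd == 0) 0 else (disp[idx] - mu) / sd
    }
    z
}

#' Highly variable gene selection
#'
#' Keeps the \code{n_top} genes with the highest binned dispersion of the
#' log1p spliced layer (variance/mean, z-scored within 20 equal-frequency
#' mean bins). Both layers are subset identically; ties and the final
#' ordering resolve towards the lower gene index.
#'
#' @param x a normalized \linkS4class{VeloSet}.
#' @param n_top number of genes to keep.
#' @return the gene-restricted \linkS4class{VeloSet}.
#' @export
selectHighlyVariableGenes <- function(x, n_top = 2000L) {
    d <- nrow(x)
    if (n_top >= d) {
        if (n_top > d)
            warning(sprintf("n_top (%d) exceeds gene count (%d); keeping all genes",
                            n_top, d))
        return(x)
    }
    z <- .dispersion_stat(as.matrix(spliced(x)))
    ord <- order(-z, seq_len(d))        # ties -> lower index first
    keep <- sort(ord[seq_len(n_top)])   # stable original order
    x[keep, ]
}

#' PCA of the (log1p) spliced layer
#'
#' Principal component scores of the centered, optionally log1p-transformed
#' spliced matrix, cells in rows. Deterministic: each component's sign is
#' fixed so that its largest-magnitude gene loading is positive.
#'
#' @param x a normalized \linkS4class{VeloSet}.
#' @param n_pcs number of components; clipped to \code{min(N-1, D)} with a
#'   warning when too large.
#' @param log log1p-transform before PCA.
#' @return \code{x} with \code{reducedDim "PCA"} set.
#' @export
computePCA <- function(x, n_pcs = 30L, log = TRUE) {
    s <- Matrix::t(spliced(x))               # cells x genes
    if (log) s <- log1p(s)
    s <- as.matrix(s)
    max_pc <- min(nrow(s) - 1L, ncol(s))
    if (n_pcs > max_pc) {
        warning(sprintf("n_pcs reduced from %d to %d", n_pcs, max_pc))
        n_pcs <- max_pc
    }
    pc <- stats::prcomp(s, center = TRUE, scale. = FALSE, rank. = n_pcs)
    rot <- pc$rotation
    flip <- vapply(seq_len(ncol(rot)), function(j) {
        w <- rot[, j]
        sign(w[which.max(abs(w))])
    }, numeric(1))
    flip[flip == 0] <- 1
    scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
    rownames(scores) <- colnames(x)
    reducedDim(x, "PCA") <- scores
    x
}

# brute-force kNN with lower-index tie-break; coords cells x dims
.knn_bruteforce <- function(coords, k) {
    n <- nrow(coords)
    dm <- as.matrix(stats::dist(coords))
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
        d <- dm[i, ]
        d[i] <- Inf
        o <- order(d, seq_len(n))[seq_len(k)]
        idx[i, ] <- o
        dst[i, ] <- d[o]
    }
    list(index = idx, distance = dst)
}

#' k-nearest-neighbour graph of cells
#'
#' Euclidean nearest neighbours in PC space (falls back to log1p spliced
#' expression with a warning when PCA has not been computed). Self is always
#' excluded; ties break towards the lower cell index.
#'
#' @param x a \linkS4class{VeloSet}.
#' @param k neighbourhood size; must be < number of cells.
#' @return a \linkS4class{NeighborGraph}.
#' @export
buildKnnGraph <- function(x, k = 30L) {
    n <- ncol(x)
    if (k >= n) stop("k must be < number of cells")
    if ("PCA" %in% reducedDimNames(x)) {
        coords <- reducedDim(x, "PCA")
        metric <- "euclidean_pca"
    } else {
        warning("no PCA found; building kNN on log1p spliced expression")
        coords <- as.matrix(Matrix::t(log1p(spliced(x))))
        metric <- "euclidean_log1p"
    }
    nn <- .knn_bruteforce(coords, as.integer(k))
    new("NeighborGraph", index = nn$index, distance = nn$distance,
        k = as.integer(k), metric = metric)
}

#' Neighbour smoothing of the count layers
#'
#' Replaces every value by the mean over the cell and its k nearest
#' neighbours (first-order moments). Smoothed layers are stored as separate
#' assays \code{"spliced_smooth"} / \code{"unspliced_smooth"}; the normalized
#' layers are untouched. The graph is recorded in the metadata for all
#' downstream steps.
#'
#' @param x a \linkS4class{VeloSet}.
#' @param graph a \linkS4class{NeighborGraph} built on \code{x}.
#' @return \code{x} with smoothed layers.
#' @export
smoothByNeighbors <- function(x, graph) {
    if (nrow(graph@index) != ncol(x))
        stop("graph and dataset disagree on the number of cells")
    m <- smoothingMatrix(graph)           # cells x cells, row-stochastic
    ss <- as.matrix(Matrix::t(m %*% Matrix::t(spliced(x))))
    us <- as.matrix(Matrix::t(m %*% Matrix::t(unspliced(x))))
    dimnames(ss) <- dimnames(us) <- dimnames(spliced(x))
    assay(x, "spliced_smooth") <- ss
    assay(x, "unspliced_smooth") <- us
    metadata(x)$neighbor_graph <- graph
    x
}

#' Full preprocessing chain
#'
#' Runs, in this fixed order: drop zero-total cells + library-size
#' normalization, highly variable gene selection on the spliced layer, PCA of
#' log1p spliced counts, kNN graph in PC space, and neighbour smoothing of
#' the normalized (non-log) layers.
#'
#' @param x a raw-count \linkS4class{VeloSet}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return the preprocessed \linkS4class{VeloSet}.
#' @export
preprocess <- function(x, config = preprocessConfig()) {
    x <- normalizeCounts(x, target = config$normalize_target)
    x <- selectHighlyVariableGenes(x, n_top = config$n_top_genes)
    x <- computePCA(x, n_pcs = config$n_pcs, log = config$log_for_pca)
    graph <- buildKnnGraph(x, k = min(config$k_neighbors, ncol(x) - 1L))
    x <- smoothByNeighbors(x, graph)
    metadata(x)$preprocess_config <- unclass(config)
    x
}
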