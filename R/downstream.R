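#' Gene-confidence filter configuration
#'
#' @param min_cs_gene minimum gene-wise continuity score; NULL (default)
#'   uses the dataset median.
#' @param min_correlation_score minimum correlation score (default 0).
#' @param residual_lower,residual_upper strict bounds on the relative
#'   regression residual (defaults 0 and 0.95).
#' @return a list of class \code{gene_filter_config}.
#' @export
geneFilterConfig <- function(min_cs_gene = NULL, min_correlation_score = 0,
                             residual_lower = 0, residual_upper = 0.95) {
    stopifnot(residual_lower < residual_upper)
    structure(list(min_cs_gene = min_cs_gene,
                   min_correlation_score = min_correlation_score,
                   residual_lower = residual_lower,
                   residual_upper = residual_upper),
              class = "gene_filter_config")
}

# relative residual of the per-gene u-on-s linear fit: RSS / TSS of u.
# Values below round-off (1e-10) snap to exactly 0 so the strict lower bound
# of the filter treats perfectly linear portraits as residual zero.
.relative_residuals <- function(S, U) {
    rr <- vapply(seq_len(nrow(S)), function(g) {
        s <- S[g, ]; u <- U[g, ]
        tss <- sum((u - mean(u))^2)
        if (tss == 0) return(0)
        fit <- stats::lm.fit(cbind(1, s), u)
        sum(fit$residuals^2) / tss
    }, numeric(1))
    rr[rr < 1e-10] <- 0
    rr
}

#' Confidence-based gene filter
#'
#' Keeps the genes that pass all three confidence filters: gene-wise
#' continuity score at least \code{min_cs_gene}, correlation score at least
#' \code{min_correlation_score}, and the relative residual of the per-gene
#' unspliced-on-spliced linear regression strictly between the bounds
#' (larger than 0 and smaller than 0.95 by default, so perfectly linear
#' phase portraits, which carry no kinetic information, are excluded along
#' with essentially unfit genes).
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param cs_gene per-gene continuity scores (\code{\link{csGene}}).
#' @param corr_scores per-gene correlation scores
#'   (\code{\link{correlationScore}}).
#' @param config a \code{\link{geneFilterConfig}}.
#' @return integer vector of gene indices.
#' @export
geneConfidenceFilter <- function(x, cs_gene, corr_scores,
                                 config = geneFilterConfig()) {
    stopifnot(length(cs_gene) == nrow(x), length(corr_scores) == nrow(x))
    min_cs <- if (is.null(config$min_cs_gene)) stats::median(cs_gene)
              else config$min_cs_gene
    rr <- .relative_residuals(as.matrix(splicedSmooth(x)),
                              as.matrix(unsplicedSmooth(x)))
    # strict bounds, with a round-off guard so residuals within 1e-9 of a
    # bound count as sitting on it (and are excluded)
    tol <- 1e-9
    keep <- which(cs_gene >= min_cs &
                  corr_scores >= config$min_correlation_score &
                  rr > config$residual_lower + tol &
                  rr < config$residual_upper - tol)
    if (length(keep) == 0)
        stop("no genes pass the confidence filters; relax the thresholds")
    keep
}

#' Velocity graph
#'
#' On each neighbour edge (i, j), the cosine similarity between cell i's
#' velocity and the expression displacement s_j - s_i, restricted to the
#' confidence-filtered genes. Also computes the Gaussian-normalized
#' transition matrix pi_ij = exp(w_ij / sigma) / sum_j exp(w_ij / sigma)
#' over each cell's neighbours.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param genes_used integer gene indices (default all genes).
#' @param sigma Gaussian normalization scale (default 0.05).
#' @return a \linkS4class{VelocityGraph}.
#' @export
velocityGraph <- function(x, velocity, graph, genes_used = seq_len(nrow(x)),
                          sigma = 0.05) {
    if (length(genes_used) == 0) stop("genes_used must be nonempty")
    if (sigma <= 0) stop("sigma must be > 0")
    V <- t(.as_vmat(velocity))[, genes_used, drop = FALSE]
    S <- t(as.matrix(splicedSmooth(x)))[, genes_used, drop = FALSE]
    idx <- graph@index
    n <- nrow(S); k <- ncol(idx)
    vnorm <- sqrt(rowSums(V^2))
    w <- matrix(0, n, k)
    for (c in seq_len(k)) {
        dS <- S[idx[, c], , drop = FALSE] - S
        dn <- sqrt(rowSums(dS^2))
        dot <- rowSums(V * dS)
        den <- vnorm * dn
        w[, c] <- ifelse(den > 0, dot / den, 0)
    }
    pi <- exp(w / sigma)
    pi <- pi / rowSums(pi)
    i <- rep(seq_len(n), k)
    j <- as.vector(idx)
    new("VelocityGraph",
        weights = sparseMatrix(i = i, j = j, x = as.vector(w), dims = c(n, n)),
        transition = sparseMatrix(i = i, j = j, x = as.vector(pi),
                                  dims = c(n, n)),
        genesUsed = as.integer(genes_used))
}

#' Project velocities onto a 2-D embedding
#'
#' Each cell's arrow is the transition-probability-weighted sum of unit
#' direction vectors towards its neighbours in the embedding, with the
#' uniform baseline 1/k subtracted so that isotropic transition
#' probabilities yield a zero arrow.
#'
#' @param vgraph a \linkS4class{VelocityGraph}.
#' @param embedding cells x 2 coordinate matrix.
#' @param center subtract the uniform baseline (default TRUE).
#' @return cells x 2 matrix of arrows.
#' @export
projectVelocity <- function(vgraph, embedding, center = TRUE) {
    embedding <- as.matrix(embedding)
    n <- nrow(vgraph@transition)
    if (nrow(embedding) != n)
        stop("embedding must have one row per cell")
    P <- vgraph@transition
    arrows <- matrix(0, n, ncol(embedding))
    Ps <- methods::as(P, "TsparseMatrix")
    ii <- Ps@i + 1L; jj <- Ps@j + 1L; pp <- Ps@x
    delta <- embedding[jj, , drop = FALSE] - embedding[ii, , drop = FALSE]
    dn <- sqrt(rowSums(delta^2))
    ok <- dn > 0
    delta[ok, ] <- delta[ok, ] / dn[ok]
    delta[!ok, ] <- 0
    ki <- tabulate(ii, nbins = n)
    wgt <- if (center) pp - 1 / ki[ii] else pp
    for (d in seq_len(ncol(embedding)))
        arrows[, d] <- as.vector(tapply(wgt * delta[, d], factor(ii, levels = seq_len(n)), sum))
    arrows[is.na(arrows)] <- 0
    arrows
}

#' Rank putative driver genes by pseudotime correlation
#'
#' Per branch (all cells when no branch labels are given), ranks genes by
#' the Pearson correlation of their smoothed spliced expression with
#' pseudotime, keeps positive correlations only, and returns the top
#' \code{top_n}.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param pt pseudotime vector (default the stored one).
#' @param branch_labels optional factor/character per cell.
#' @param top_n rows per branch (default 100).
#' @return data.frame with columns \code{branch}, \code{gene},
#'   \code{correlation}, \code{rank}.
#' @export
rankDriverGenes <- function(x, pt = pseudotime(x), branch_labels = NULL,
                            top_n = 100L) {
    if (is.null(pt)) stop("pseudotime is required")
    S <- as.matrix(splicedSmooth(x))
    branches <- if (is.null(branch_labels)) rep("all", ncol(x))
                else as.character(branch_labels)
    out <- list()
    for (b in unique(branches)) {
        sel <- which(branches == b & is.finite(pt))
        if (length(sel) < 3)
            stop(sprintf("branch '%s' has fewer than 3 cells with finite pseudotime", b))
        ptb <- pt[sel]
        cors <- vapply(seq_len(nrow(S)), function(g) {
            sg <- S[g, sel]
            if (stats::sd(sg) == 0 || stats::sd(ptb) == 0) return(NA_real_)
            stats::cor(sg, ptb)
        }, numeric(1))
        posi <- which(!is.na(cors) & cors > 0)
        if (length(posi) == 0) {
            warning(sprintf("branch '%s': no positively correlated genes", b))
            next
        }
        o <- posi[order(-cors[posi])]
        o <- o[seq_len(min(top_n, length(o)))]
        out[[b]] <- data.frame(branch = b, gene = rownames(x)[o],
                               correlation = cors[o],
                               rank = seq_along(o), row.names = NULL)
    }
    if (length(out) == 0)
        return(data.frame(branch = character(0), gene = character(0),
                          correlation = numeric(0), rank = integer(0)))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
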