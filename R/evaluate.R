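# unit-normalize matrix rows; zero rows -> NA rows (skipped in cosine means)
.unit_rows <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    out <- m / nrm
    out[nrm == 0, ] <- NA_real_
    out
}

.as_vmat <- function(velocity) {
    if (is(velocity, "VelocityEstimate")) velocity@v else as.matrix(velocity)
}

#' Overall velocity consistency
#'
#' Per cell, the average cosine similarity between its velocity vector and
#' those of its k nearest neighbours (the preprocessing graph). Terms with a
#' zero-velocity participant are skipped with the denominator reduced;
#' cells whose own velocity is zero (or with no valid neighbour term) are NA.
#'
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param graph a \linkS4class{NeighborGraph}.
#' @return numeric vector in [-1, 1], length = number of cells.
#' @export
overallConsistency <- function(velocity, graph) {
    V <- t(.as_vmat(velocity))          # cells x genes
    vn <- .unit_rows(V)
    idx <- graph@index
    n <- nrow(vn)
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (anyNA(vn[i, ])) next
        cs <- vn[idx[i, ], , drop = FALSE] %*% vn[i, ]
        out[i] <- mean(cs, na.rm = TRUE)
        if (is.nan(out[i])) out[i] <- NA_real_
    }
    out
}

#' Cell-type-wise velocity consistency
#'
#' Per cell, the average cosine similarity of its velocity to the velocities
#' of all cells of the same type, including itself (so a singleton type
#' scores 1).
#'
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param cell_type factor/character of labels per cell.
#' @return numeric vector in [-1, 1].
#' @export
celltypeConsistency <- function(velocity, cell_type) {
    if (is.null(cell_type)) stop("cell_type labels are required")
    V <- t(.as_vmat(velocity))
    if (length(cell_type) != nrow(V))
        stop("cell_type length must equal the number of cells")
    vn <- .unit_rows(V)
    out <- rep(NA_real_, nrow(V))
    for (ty in unique(cell_type)) {
        sel <- which(cell_type == ty)
        sub <- vn[sel, , drop = FALSE]
        ok <- !is.na(sub[, 1])
        if (!any(ok)) next
        tot <- colSums(sub[ok, , drop = FALSE])
        cs <- (sub %*% tot) / sum(ok)
        out[sel] <- as.numeric(cs)
    }
    out
}

#' Per-cell, per-gene continuity error
#'
#' Relative absolute deviation between the extrapolated state s + v and the
#' probability-weighted candidate expression, with the denominator floored
#' at \code{eps0} to keep the score finite on zero-expression entries.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param targets a forward \linkS4class{TargetDistribution} from the final
#'   velocity (recomputed when NULL).
#' @param eps0 denominator floor (default 1e-3 on the normalized scale).
#' @return genes x cells nonnegative matrix.
#' @export
continuityError <- function(x, velocity, targets = NULL, eps0 = 1e-3) {
    V <- t(.as_vmat(velocity))
    S <- t(as.matrix(splicedSmooth(x)))
    if (is.null(targets))
        targets <- candidateTargetProbabilities(x, neighborGraph(x),
                                                velocity, "forward")
    Tm <- .weighted_targets(S, targets@candidates, targets@prob)
    eps <- abs(S + V - Tm) / pmax(S, eps0)
    t(eps)
}

#' Cell-wise continuity score
#'
#' CS-cell_i = 1 - mean over genes of tanh(eps_i,g); 1 iff the continuity
#' assumption is met exactly, approaching 0 as errors grow.
#'
#' @param eps genes x cells error matrix from \code{\link{continuityError}}.
#' @return numeric vector over cells, in (0, 1].
#' @export
csCell <- function(eps) 1 - colMeans(tanh(eps))

#' Gene-wise continuity score
#'
#' CS-gene_g = 1 - mean over cells of tanh(eps_i,g).
#'
#' @param eps genes x cells error matrix from \code{\link{continuityError}}.
#' @return numeric vector over genes, in (0, 1].
#' @export
csGene <- function(eps) 1 - rowMeans(tanh(eps))

#' Per-gene correlation score
#'
#' corr(v, u) + corr(v, -s) across cells for each gene, on the smoothed
#' layers; terms with zero variance in either argument contribute 0. High
#' scores indicate velocities in line with the kinetic heuristic (positive
#' with unspliced, negative with spliced expression).
#'
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param x a preprocessed \linkS4class{VeloSet} (>= 2 cells).
#' @return numeric vector over genes, in [-2, 2].
#' @export
correlationScore <- function(velocity, x) {
    if (ncol(x) < 2) stop("correlationScore needs at least 2 cells")
    V <- t(.as_vmat(velocity))
    pt <- .pearson_terms(V, t(as.matrix(unsplicedSmooth(x))),
                         t(as.matrix(splicedSmooth(x))), 1, 1)
    out <- pt$corr_u + pt$corr_s
    names(out) <- rownames(x)
    out
}

#' Boundary cells of an annotated cell-type transition
#'
#' The cells of type A having at least one type-B cell among their k nearest
#' neighbours (the preprocessing graph).
#'
#' @param x a \linkS4class{VeloSet} with \code{cell_type} labels.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param pair character of length 2, c(from = A, to = B).
#' @return integer vector of cell indices.
#' @export
boundaryCells <- function(x, graph, pair) {
    ct <- cellType(x)
    if (is.null(ct)) stop("cell_type labels are required")
    if (!all(pair %in% ct))
        stop(sprintf("unknown cell type label(s): %s",
                     paste(setdiff(pair, ct), collapse = ", ")))
    a_cells <- which(ct == pair[1])
    is_b <- ct[as.vector(graph@index)] == pair[2]
    has_b <- rowSums(matrix(is_b, nrow(graph@index))) > 0
    a_cells[has_b[a_cells]]
}

#' Direction score against annotated cell-type relations
#'
#' For each boundary cell i of a pair (A, B), the mean cosine between the
#' velocity and the displacement s_j - s_i over the B-neighbours j. As
#' printed, the neighbour's velocity v_j is used; \code{velocity_of="cell"}
#' switches to the conventional cross-boundary form using v_i. The global
#' score is the unweighted mean over the union of boundary cells across all
#' pairs (cells in several pairs count once, with their per-pair scores
#' averaged), not a mean of per-pair means.
#'
#' @param x a preprocessed \linkS4class{VeloSet} with cell types.
#' @param velocity a \linkS4class{VelocityEstimate} or genes x cells matrix.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param pairs list of character pairs c(A, B).
#' @param velocity_of \code{"neighbor"} (printed form) or \code{"cell"}.
#' @return list with \code{boundary_cells} (per pair), \code{per_cell}
#'   (named vector over the union), and \code{global}.
#' @export
directionScore <- function(x, velocity, graph, pairs,
                           velocity_of = c("neighbor", "cell")) {
    velocity_of <- match.arg(velocity_of)
    if (is.character(pairs)) pairs <- list(pairs)
    ct <- cellType(x)
    V <- t(.as_vmat(velocity))
    S <- t(as.matrix(splicedSmooth(x)))
    vn <- .unit_rows(V)
    idx <- graph@index
    per_pair <- list()
    bcl <- list()
    for (p in seq_along(pairs)) {
        pair <- pairs[[p]]
        bc <- boundaryCells(x, graph, pair)
        bcl[[paste(pair, collapse = "->")]] <- bc
        sc <- rep(NA_real_, length(bc))
        for (q in seq_along(bc)) {
            i <- bc[q]
            nb <- idx[i, ][ct[idx[i, ]] == pair[2]]
            terms <- vapply(nb, function(j) {
                dv <- S[j, ] - S[i, ]
                dn <- sqrt(sum(dv^2))
                vrow <- if (velocity_of == "neighbor") vn[j, ] else vn[i, ]
                if (dn == 0 || anyNA(vrow)) return(NA_real_)
                sum(vrow * dv) / dn
            }, numeric(1))
            if (any(!is.na(terms))) sc[q] <- mean(terms, na.rm = TRUE)
        }
        per_pair[[p]] <- stats::setNames(sc, bc)
    }
    union_cells <- sort(unique(unlist(bcl)))
    if (length(union_cells) == 0)
        stop("no boundary cells for given pairs")
    per_cell <- vapply(union_cells, function(i) {
        vals <- unlist(lapply(per_pair, function(sp) sp[as.character(i)]))
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1))
    names(per_cell) <- union_cells
    list(boundary_cells = bcl, per_cell = per_cell,
         global = mean(per_cell, na.rm = TRUE))
}
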