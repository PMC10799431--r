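suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(SingleCellExperiment)
    library(Matrix)
})

# tiny deterministic dataset with both layers and explicit names
toy_veloset <- function(n_genes = 3, n_cells = 5, seed = 42) {
    set.seed(seed)
    s <- matrix(rpois(n_genes * n_cells, 8) + 1, n_genes, n_cells)
    u <- matrix(rpois(n_genes * n_cells, 4) + 1, n_genes, n_cells)
    rownames(s) <- sprintf("g%d", seq_len(n_genes))
    colnames(s) <- sprintf("c%d", seq_len(n_cells))
    VeloSet(spliced = s, unspliced = u)
}

# dataset with smoothed layers set directly (identity smoothing), for metric
# fixtures where exact values matter
fixture_veloset <- function(s, u = s * 0 + 1, cell_type = NULL,
                            pseudotime = NULL) {
    rownames(s) <- rownames(u) <- sprintf("g%d", seq_len(nrow(s)))
    colnames(s) <- colnames(u) <- sprintf("c%d", seq_len(ncol(s)))
    vs <- VeloSet(spliced = pmax(s, 0), unspliced = pmax(u, 0),
                  cell_type = cell_type, pseudotime = pseudotime)
    assay(vs, "spliced_smooth") <- s
    assay(vs, "unspliced_smooth") <- u
    vs
}

# neighbour graph from explicit index matrix
graph_from_index <- function(idx, dist = NULL) {
    idx <- matrix(as.integer(idx), nrow(idx))
    if (is.null(dist)) dist <- matrix(0, nrow(idx), ncol(idx))
    new("NeighborGraph", index = idx, distance = dist,
        k = ncol(idx), metric = "fixture")
}

# fixed-step RK4 oracle for the splicing ODE, splitting exactly at the
# transcription switch so the discontinuity costs no accuracy
rk4_kinetics <- function(alpha, beta, gamma_fn, t_end, u0 = 0, s0 = 0,
                         t_switch = Inf, dt = 1e-4) {
    if (!is.function(gamma_fn)) {
        gval <- gamma_fn
        gamma_fn <- function(t) gval
    }
    integrate_piece <- function(a, t0, t1, u, s) {
        f <- function(t, u, s) c(a - beta * u, beta * u - gamma_fn(t) * s)
        t <- t0
        while (t < t1 - 1e-12) {
            h <- min(dt, t1 - t)
            k1 <- f(t, u, s)
            k2 <- f(t + h / 2, u + h / 2 * k1[1], s + h / 2 * k1[2])
            k3 <- f(t + h / 2, u + h / 2 * k2[1], s + h / 2 * k2[2])
            k4 <- f(t + h, u + h * k3[1], s + h * k3[2])
            inc <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
            u <- u + h * inc[1]
            s <- s + h * inc[2]
            t <- t + h
        }
        c(u, s)
    }
    if (t_end <= t_switch) {
        st <- integrate_piece(alpha, 0, t_end, u0, s0)
    } else {
        st <- integrate_piece(alpha, 0, t_switch, u0, s0)
        st <- integrate_piece(0, t_switch, t_end, st[1], st[2])
    }
    list(u = st[1], s = st[2])
}

# naive loop implementation of the continuity objective (candidate
# probabilities by explicit cosine, extrapolation losses, Pearson term) --
# the independent oracle for the vectorized implementation
naive_total_loss <- function(S, U, idx, V, w_f = 1, w_b = 1, w_p = 18,
                             lambda_u = 1, lambda_s = 1) {
    n <- nrow(S)
    d <- ncol(S)
    k <- ncol(idx)
    cosim <- function(a, b) {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0 || nb == 0) return(0)
        sum(a * b) / (na * nb)
    }
    loss_dir <- function(sgn) {
        terms <- 0
        n_active <- 0
        for (i in seq_len(n)) {
            pos <- logical(k)
            for (c in seq_len(k)) {
                j <- idx[i, c]
                pos[c] <- cosim(S[j, ] - S[i, ], sgn * V[i, ]) > 0
            }
            z <- sum(pos)
            if (z == 0) next
            n_active <- n_active + 1
            target <- rep(0, d)
            for (c in which(pos)) target <- target + S[idx[i, c], ] / z
            terms <- terms + sum((S[i, ] + sgn * V[i, ] - target)^2)
        }
        if (n_active == 0) 0 else terms / (n_active * d)
    }
    pear <- function() {
        cu <- cs <- numeric(0)
        for (g in seq_len(d)) {
            if (sd(V[, g]) > 0 && sd(U[, g]) > 0)
                cu <- c(cu, cor(V[, g], U[, g]))
            if (sd(V[, g]) > 0 && sd(S[, g]) > 0)
                cs <- c(cs, cor(V[, g], -S[, g]))
        }
        -(lambda_u * (if (length(cu)) mean(cu) else 0) +
          lambda_s * (if (length(cs)) mean(cs) else 0))
    }
    lf <- loss_dir(1)
    lb <- loss_dir(-1)
    lp <- pear()
    list(loss_forward = lf, loss_backward = lb, loss_pearson = lp,
         total = w_f * lf + w_b * lb + w_p * lp)
}

# preprocessing used for simulated abundances: no depth normalization
sim_preprocess <- function(vs, n_pcs = 30, k = 30) {
    preprocess(vs, preprocessConfig(n_top_genes = nrow(vs), n_pcs = n_pcs,
                                    k_neighbors = min(k, ncol(vs) - 1L),
                                    normalize_target = "none"))
}

# pseudotime bins as pseudo cell-types plus consecutive pairs
pseudotime_pairs <- function(vs, n_bins = 5) {
    pt <- pseudotime(vs)
    labs <- paste0("bin", seq_len(n_bins))
    colData(vs)$cell_type <- as.character(cut(pt, breaks = n_bins,
                                              labels = labs))
    list(vs = vs,
         pairs = lapply(seq_len(n_bins - 1),
                        function(i) c(labs[i], labs[i + 1])))
}
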