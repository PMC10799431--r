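test_that("overall consistency matches hand cosine arithmetic", {
    # velocities (1,0), (0,1), (1,1) on a full neighbour graph
    v <- t(rbind(c(1, 0), c(0, 1), c(1, 1)))   # genes x cells
    g <- graph_from_index(rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
    cs <- overallConsistency(v, g)
    r2 <- sqrt(2) / 2
    expect_equal(cs, c(r2 / 2, r2 / 2, r2), tolerance = 1e-10)

    # one shared vector -> all ones
    vsame <- matrix(c(1, 2), 2, 4)
    g4 <- graph_from_index(rbind(c(2L, 3L), c(3L, 4L), c(4L, 1L), c(1L, 2L)))
    expect_equal(overallConsistency(vsame, g4), rep(1, 4))

    # neighbours all opposite -> -1; zero velocity -> NA
    vop <- t(rbind(c(1, 0), c(-1, 0), c(-1, 0)))
    expect_equal(overallConsistency(vop, g)[1], -1)
    vz <- t(rbind(c(0, 0), c(1, 0), c(1, 0)))
    expect_true(is.na(overallConsistency(vz, g)[1]))
})

test_that("cell-type consistency includes the self term", {
    v <- t(rbind(c(1, 0), c(-1, 0), c(0, 2)))
    # singleton type scores 1 by its self term
    expect_equal(celltypeConsistency(v, c("a", "b", "c")), rep(1, 3))
    # two opposite velocities in one type -> (1 + (-1)) / 2 = 0 each
    expect_equal(celltypeConsistency(v, c("a", "a", "b")),
                 c(0, 0, 1))
    # identical velocities -> 1
    vsame <- matrix(c(3, 1), 2, 3)
    expect_equal(celltypeConsistency(vsame, rep("t", 3)), rep(1, 3))
    expect_error(celltypeConsistency(v, NULL), "required")
})

test_that("continuity error and scores follow their closed forms", {
    # s=1, v=1, single target 3 -> eps = |1+1-3|/1 = 1
    s <- matrix(c(1, 3), 1, 2)
    vs <- fixture_veloset(s)
    v <- matrix(c(1, 0), 1, 2)
    g <- graph_from_index(rbind(2L, 1L))
    tf <- candidateTargetProbabilities(vs, g, v, "forward")
    eps <- continuityError(vs, v, tf)
    expect_equal(eps[1, 1], 1)

    # perfect extrapolation -> eps 0 -> CS = 1
    s2 <- matrix(c(1, 2), 1, 2)
    vs2 <- fixture_veloset(s2)
    tf2 <- candidateTargetProbabilities(vs2, g, v, "forward")
    eps2 <- continuityError(vs2, v, tf2)
    expect_equal(eps2[1, 1], 0)
    expect_equal(csCell(matrix(0, 2, 3)), rep(1, 3))

    # tanh closed form: eps = ln 3 -> tanh = 0.8 -> CS = 0.2
    expect_equal(csCell(matrix(log(3), 1, 1)), 0.2, tolerance = 1e-12)
    expect_equal(csGene(matrix(log(3), 1, 1)), 0.2, tolerance = 1e-12)
    # saturation: huge errors drive CS to 0
    expect_lt(max(csCell(matrix(50, 4, 2))), 1e-10)

    # denominator floor keeps zero-expression entries finite
    s3 <- matrix(c(0, 1), 1, 2)
    vs3 <- fixture_veloset(s3)
    tf3 <- candidateTargetProbabilities(vs3, g, matrix(c(1, 0), 1, 2),
                                        "forward")
    eps3 <- continuityError(vs3, matrix(c(1, 0), 1, 2), tf3, eps0 = 1e-3)
    expect_true(all(is.finite(eps3)))

    # strict monotonicity: increasing any eps entry lowers the scores
    e <- matrix(runif(12), 3, 4)
    e2 <- e; e2[2, 3] <- e2[2, 3] + 0.5
    expect_lt(csCell(e2)[3], csCell(e)[3])
    expect_lt(csGene(e2)[2], csGene(e)[2])
})

test_that("correlation score adds the u- and s-correlations per gene", {
    n <- 40
    set.seed(51)
    u <- matrix(runif(n), 1, n)
    vs <- fixture_veloset(matrix(1, 1, n), u)        # constant s
    expect_equal(unname(correlationScore(2 * u, vs)), 1)   # corr_u 1, s-term 0

    su <- matrix(runif(n), 1, n)
    vs2 <- fixture_veloset(su, -su + 2)              # u anti-correlated with s
    expect_equal(unname(correlationScore(su, vs2)), -2)    # v ~ -u and v ~ s

    # independent random velocity: null width at n = 500
    set.seed(53)
    n2 <- 500
    vs3 <- fixture_veloset(matrix(runif(n2), 1, n2), matrix(runif(n2), 1, n2))
    null_scores <- replicate(20, unname(correlationScore(
        matrix(rnorm(n2), 1, n2), vs3)))
    expect_lt(max(abs(null_scores)), 0.5)
})

test_that("boundary cells are exactly the A-cells with a B neighbour", {
    ct <- c("A", "A", "A", "B", "B")
    s <- matrix(seq_len(5), 1, 5)
    vs <- fixture_veloset(s, cell_type = ct)
    # neighbours: 1->2, 2->3, 3->4(B), 4->5, 5->4
    g <- graph_from_index(rbind(2L, 3L, 4L, 5L, 4L))
    expect_identical(boundaryCells(vs, g, c("A", "B")), 3L)
    expect_error(boundaryCells(vs, g, c("A", "Z")), "unknown")
    # all cells type A -> empty
    vsa <- fixture_veloset(s, cell_type = rep("A", 5))
    expect_error(boundaryCells(vsa, g, c("A", "B")), "unknown")
    vsab <- fixture_veloset(s, cell_type = c("A", "A", "A", "A", "B"))
    g2 <- graph_from_index(rbind(2L, 1L, 2L, 3L, 4L))  # no A has B neighbour
    expect_length(boundaryCells(vsab, g2, c("A", "B")), 0)
})

test_that("direction score is signed alignment and uses union weighting", {
    # 9 A->B pairs with perfect alignment, 1 C->D pair anti-aligned:
    # global must be (9 - 1) / 10 = 0.8, not the per-pair mean 0
    nA <- 9
    pos <- matrix(0, 2, 2 * nA + 2)
    v <- matrix(0, 2, 2 * nA + 2)
    ct <- character(2 * nA + 2)
    idx <- integer(2 * nA + 2)
    for (i in seq_len(nA)) {
        a <- 2 * i - 1; b <- 2 * i
        pos[, a] <- c(0, 10 * i); pos[, b] <- c(1, 10 * i)
        v[, b] <- c(1, 0)                       # neighbour velocity along +x
        ct[a] <- "A"; ct[b] <- "B"
        idx[a] <- b; idx[b] <- a
    }
    cc <- 2 * nA + 1; dd <- 2 * nA + 2
    pos[, cc] <- c(0, 1000); pos[, dd] <- c(1, 1000)
    v[, dd] <- c(-1, 0)                         # anti-aligned
    ct[cc] <- "C"; ct[dd] <- "D"
    idx[cc] <- dd; idx[dd] <- cc
    vs <- fixture_veloset(pos)
    colData(vs)$cell_type <- ct
    g <- graph_from_index(matrix(idx, ncol = 1))
    ds <- directionScore(vs, v, g, list(c("A", "B"), c("C", "D")))
    expect_equal(unname(ds$per_cell), c(rep(1, nA), -1))
    expect_equal(ds$global, 0.8)

    # velocity_of = "cell" uses the boundary cell's own velocity
    v2 <- v
    v2[, seq(1, 2 * nA, by = 2)] <- c(1, 0)     # A-cell velocities +x
    v2[, cc] <- c(-1, 0)
    ds2 <- directionScore(vs, v2, g, list(c("A", "B"), c("C", "D")),
                          velocity_of = "cell")
    expect_equal(ds2$global, 0.8)

    expect_error(directionScore(vs, v, g, list(c("B", "C"))), "no boundary")
})

test_that("cosine metrics are invariant to positive velocity rescaling", {
    set.seed(59)
    v <- matrix(rnorm(40), 4, 10)
    g <- graph_from_index(cbind(c(2:10, 1L), c(3:10, 1:2)))
    expect_equal(overallConsistency(v, g), overallConsistency(5 * v, g),
                 tolerance = 1e-12)
    ct <- rep(c("x", "y"), 5)
    expect_equal(celltypeConsistency(v, ct), celltypeConsistency(5 * v, ct),
                 tolerance = 1e-12)
})

test_that("overall consistency equals the brute-force double loop", {
    set.seed(61)
    n <- 50
    v <- matrix(rnorm(3 * n), 3, n)
    v[, 7] <- 0
    idx <- t(vapply(seq_len(n), function(i)
        sample(setdiff(seq_len(n), i), 6), integer(6)))
    g <- graph_from_index(idx)
    got <- overallConsistency(v, g)
    for (i in seq_len(n)) {
        vi <- v[, i]
        if (sqrt(sum(vi^2)) == 0) {
            expect_true(is.na(got[i]))
            next
        }
        terms <- vapply(idx[i, ], function(j) {
            vj <- v[, j]
            nj <- sqrt(sum(vj^2))
            if (nj == 0) return(NA_real_)
            sum(vi * vj) / (sqrt(sum(vi^2)) * nj)
        }, numeric(1))
        expect_equal(got[i], mean(terms, na.rm = TRUE), tolerance = 1e-10)
    }
})

test_that("ground-truth velocity aligns with pseudotime-ordered bins on a
           noise-free simulation", {
    vs <- simulatePopulation(300, 12, noise_sd = 0, seed = 67)
    vs <- sim_preprocess(vs, n_pcs = 10, k = 20)
    pp <- pseudotime_pairs(vs)
    ds <- directionScore(pp$vs, assay(vs, "true_velocity"),
                         neighborGraph(vs), pp$pairs)
    expect_gte(mean(ds$per_cell > 0, na.rm = TRUE), 0.9)
})
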