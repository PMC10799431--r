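test_that("candidate probabilities follow the positive-cosine rule", {
    # cell 1 at origin with velocity (1,0); candidates at (1,0), (-1,0), (0,1)
    s <- t(rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1)))   # genes x cells
    vs <- fixture_veloset(s + 2)                          # shift keeps >= 0
    v <- matrix(0, 2, 4)
    v[, 1] <- c(1, 0)
    g <- graph_from_index(rbind(c(2L, 3L, 4L), c(1L, 3L, 4L),
                                c(1L, 2L, 4L), c(1L, 2L, 3L)))
    fwd <- candidateTargetProbabilities(vs, g, v, "forward")
    expect_equal(fwd@prob[1, ], c(1, 0, 0))   # cosines 1, -1, 0
    expect_identical(fwd@z[1], 1L)
    bwd <- candidateTargetProbabilities(vs, g, v, "backward")
    expect_equal(bwd@prob[1, ], c(0, 1, 0))

    # zero velocity -> Z = 0, all-zero row
    expect_identical(fwd@z[2], 0L)
    expect_equal(fwd@prob[2, ], c(0, 0, 0))

    # probabilities are exactly {0, 1/Z} and rows sum to 1 or 0
    set.seed(17)
    vs2 <- sim_preprocess(simulatePopulation(50, 5, seed = 17), n_pcs = 4,
                          k = 8)
    v2 <- matrix(rnorm(250), 5, 50)
    td <- candidateTargetProbabilities(vs2, neighborGraph(vs2), v2, "forward")
    for (i in seq_len(50)) {
        row <- td@prob[i, ]
        if (td@z[i] == 0L) expect_equal(row, rep(0, 8))
        else expect_true(all(row %in% c(0, 1 / td@z[i])))
    }
    expect_true(all(abs(rowSums(td@prob)[td@z > 0] - 1) < 1e-8))
})

test_that("continuity loss matches hand evaluation", {
    # 1-gene toy: s=1, v=1, single candidate s_j=3 -> (1+1-3)^2 = 1
    s <- matrix(c(1, 3), 1, 2)
    vs <- fixture_veloset(s)
    v <- matrix(c(1, 0), 1, 2)
    g <- graph_from_index(rbind(2L, 1L))
    tf <- candidateTargetProbabilities(vs, g, v, "forward")
    expect_identical(tf@z, c(1L, 0L))
    expect_equal(continuityLoss(vs, v, tf), 1)

    # perfect extrapolation -> 0
    s2 <- matrix(c(1, 2), 1, 2)
    vs2 <- fixture_veloset(s2)
    tf2 <- candidateTargetProbabilities(vs2, g, v, "forward")
    expect_equal(continuityLoss(vs2, v, tf2), 0)

    # two candidates at 1/2 each whose mean equals the extrapolation -> 0
    s3 <- matrix(c(1, 2.5, 1.5), 1, 3)
    vs3 <- fixture_veloset(s3)
    g3 <- graph_from_index(rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
    v3 <- matrix(c(1, 0, 0), 1, 3)
    tf3 <- candidateTargetProbabilities(vs3, g3, v3, "forward")
    expect_equal(tf3@prob[1, ], c(0.5, 0.5))
    expect_equal(continuityLoss(vs3, v3, tf3), 0)
})

test_that("Pearson loss honours correlations and variance guards", {
    n <- 20
    set.seed(3)
    u <- matrix(runif(n), 1, n)
    s <- matrix(1, 1, n)               # constant spliced: s-term guarded
    vs <- fixture_veloset(s, u)
    expect_equal(pearsonLoss(u, vs), -1)            # v = u -> corr 1
    expect_equal(pearsonLoss(-u, vs), 1)            # v = -u -> corr -1
    expect_equal(pearsonLoss(matrix(2, 1, n), vs), 0)  # constant v -> 0

    # lambda weighting
    su <- matrix(runif(n), 1, n)
    vs2 <- fixture_veloset(su, su)
    expect_equal(pearsonLoss(su, vs2, lambda_u = 2, lambda_s = 3),
                 -(2 * 1 + 3 * (-1)))
    expect_error(pearsonLoss(matrix(1, 1, 1), fixture_veloset(matrix(1, 1, 1))),
                 "2 cells")
})

test_that("total loss combines components with the configured weights", {
    set.seed(23)
    vs <- sim_preprocess(simulatePopulation(30, 4, seed = 23), n_pcs = 3,
                         k = 5)
    g <- neighborGraph(vs)
    v <- matrix(rnorm(4 * 30), 4, 30)
    cfg <- objectiveConfig(weight_forward = 1, weight_backward = 1,
                           weight_pearson = 18)
    lb <- totalLoss(vs, g, v, cfg)
    expect_equal(lb$total,
                 lb$loss_forward + lb$loss_backward + 18 * lb$loss_pearson,
                 tolerance = 1e-12)
    # weight_pearson = 0 removes the dependence on the Pearson term
    lb0 <- totalLoss(vs, g, v, objectiveConfig(weight_pearson = 0))
    expect_equal(lb0$total, lb0$loss_forward + lb0$loss_backward,
                 tolerance = 1e-12)
})

test_that("vectorized objective equals the naive loop oracle", {
    set.seed(29)
    for (r in 1:3) {
        n <- sample(30:80, 1)
        d <- sample(3:12, 1)
        k <- sample(3:10, 1)
        vs <- sim_preprocess(simulatePopulation(n, d, seed = 29 + r),
                             n_pcs = min(d, 5), k = k)
        g <- neighborGraph(vs)
        v <- matrix(rnorm(n * d), d, n)
        got <- totalLoss(vs, g, v, objectiveConfig())
        want <- naive_total_loss(t(as.matrix(splicedSmooth(vs))),
                                 t(as.matrix(unsplicedSmooth(vs))),
                                 g@index, t(v))
        expect_equal(got$loss_forward, want$loss_forward, tolerance = 1e-8)
        expect_equal(got$loss_backward, want$loss_backward, tolerance = 1e-8)
        expect_equal(got$loss_pearson, want$loss_pearson, tolerance = 1e-8)
        expect_equal(got$total, want$total, tolerance = 1e-8)
    }
})

test_that("without the Pearson term the objective is blind to the
           velocity sign; with it it is not", {
    set.seed(31)
    vs <- sim_preprocess(simulatePopulation(40, 5, seed = 31), n_pcs = 4,
                         k = 10)
    g <- neighborGraph(vs)
    v <- matrix(rnorm(5 * 40), 5, 40)
    no_p <- objectiveConfig(weight_pearson = 0)
    expect_equal(totalLoss(vs, g, v, no_p)$total,
                 totalLoss(vs, g, -v, no_p)$total, tolerance = 1e-10)
    with_p <- objectiveConfig(weight_pearson = 18)
    expect_false(isTRUE(all.equal(totalLoss(vs, g, v, with_p)$total,
                                  totalLoss(vs, g, -v, with_p)$total,
                                  tolerance = 1e-10)))
})

test_that("backpropagated gradients match finite differences", {
    vs <- sim_preprocess(simulatePopulation(25, 4, seed = 37), n_pcs = 3,
                         k = 5)
    g <- neighborGraph(vs)
    model <- initGcnModel(vs, g, modelConfig(hidden_sizes = c(5, 4),
                                             dropout = 0, seed = 11))
    S <- t(as.matrix(splicedSmooth(vs)))
    U <- t(as.matrix(unsplicedSmooth(vs)))
    X <- cbind(S, U)
    cfg <- objectiveConfig()
    lg <- velogcn:::.loss_and_grads(model, X, S, U, g@index, cfg,
                                    training = FALSE)
    h <- 1e-6
    set.seed(41)
    for (nm in names(model@weights)) {
        for (i in sample(length(model@weights[[nm]]),
                         min(3, length(model@weights[[nm]])))) {
            m1 <- model; m1@weights[[nm]][i] <- m1@weights[[nm]][i] + h
            m2 <- model; m2@weights[[nm]][i] <- m2@weights[[nm]][i] - h
            num <- (velogcn:::.loss_and_grads(m1, X, S, U, g@index, cfg,
                                              training = FALSE)$loss$total -
                    velogcn:::.loss_and_grads(m2, X, S, U, g@index, cfg,
                                              training = FALSE)$loss$total) /
                   (2 * h)
            expect_lt(abs(lg$grads[[nm]][i] - num),
                      1e-5 * max(1, abs(num)))
        }
    }
})

test_that("training reduces the loss, is seed-deterministic, and freezes
           at zero learning rate", {
    vs <- sim_preprocess(simulatePopulation(200, 8, seed = 43), n_pcs = 8,
                         k = 15)
    fit <- trainVelocityModel(vs, objective_config = objectiveConfig(epochs = 60),
                              seed = 2)
    lg <- fit$log$total
    expect_lt(median(tail(lg, 10)), median(head(lg, 10)))

    fit2 <- trainVelocityModel(vs, objective_config = objectiveConfig(epochs = 60),
                               seed = 2)
    expect_identical(fit$log, fit2$log)
    expect_identical(fit$model@weights, fit2$model@weights)

    frozen <- trainVelocityModel(vs,
        model_config = modelConfig(dropout = 0),
        objective_config = objectiveConfig(epochs = 5, learning_rate = 0),
        seed = 2)
    expect_equal(var(frozen$log$total), 0, tolerance = 1e-20)
})
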