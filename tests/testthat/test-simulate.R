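test_that("constant-rate closed form hits the ODE fixed point", {
    kin <- geneKinetics(alpha = 2, beta = 1, gamma = 0.5)
    res <- solveConstantKinetics(kin, c(0, 200))
    expect_equal(res$u[2], 2 / 1, tolerance = 1e-9)     # u* = alpha / beta
    expect_equal(res$s[2], 2 / 0.5, tolerance = 1e-9)   # s* = alpha / gamma
    expect_equal(res$v[2], 0, tolerance = 1e-9)

    # starting at equilibrium stays there
    eq <- solveConstantKinetics(kin, seq(0, 5, by = 0.5), u0 = 2, s0 = 4)
    expect_equal(eq$u, rep(2, 11), tolerance = 1e-12)
    expect_equal(eq$s, rep(4, 11), tolerance = 1e-12)

    expect_error(solveConstantKinetics(geneKinetics(1, 1, 1), c(2, 1)),
                 "nondecreasing")
    expect_error(geneKinetics(1, 0, 1), "beta")
    expect_error(geneKinetics(1, 1, -1), "gamma")
})

test_that("closed form agrees with the RK4 oracle, including the
           switch and the beta = gamma limit", {
    cases <- list(list(a = 1, b = 2, g = 1, t = 1, ts = Inf),
                  list(a = 3, b = 0.7, g = 0.2, t = 3, ts = 1.5),
                  list(a = 2, b = 0.5, g = 0.5, t = 2, ts = Inf),
                  list(a = 5, b = 0.3, g = 0.31, t = 6, ts = 2.5))
    for (cs in cases) {
        kin <- geneKinetics(cs$a, cs$b, cs$g, t_switch = cs$ts)
        cf <- solveConstantKinetics(kin, cs$t)
        or <- rk4_kinetics(cs$a, cs$b, cs$g, cs$t, t_switch = cs$ts)
        expect_equal(cf$u, or$u, tolerance = 1e-6)
        expect_equal(cf$s, or$s, tolerance = 1e-6)
    }
})

test_that("time-dependent integration is consistent and monotone in gamma", {
    # constant gamma(t) reproduces the closed form
    kin <- geneKinetics(1, 2, 1, gamma_fn = function(t) 1)
    td <- solveTimeDependentKinetics(kin, c(0, 0.5, 1))
    cf <- solveConstantKinetics(geneKinetics(1, 2, 1), c(0, 0.5, 1))
    expect_equal(td$u, cf$u, tolerance = 1e-6)
    expect_equal(td$s, cf$s, tolerance = 1e-6)

    # increasing gamma with transcription off: s eventually decreasing,
    # checked by the integrator and an independent finite difference
    kin2 <- geneKinetics(4, 0.8, 0.2, t_switch = 3,
                         gamma_fn = function(t) 0.2 * (1 + 4 * t / 10))
    tt <- seq(0, 10, by = 0.05)
    res <- solveTimeDependentKinetics(kin2, tt)
    late <- tt > 6
    expect_lt(max(res$v[late]), 0)
    fd <- diff(res$s) / diff(tt)
    expect_lt(max(fd[late[-1]]), 0)
    # ds/dt from the state equation matches the finite difference
    mid_v <- (res$v[-1] + res$v[-length(res$v)]) / 2
    expect_equal(fd, mid_v, tolerance = 1e-3)

    # doubled gamma -> strictly smaller late-time s
    kin3 <- geneKinetics(4, 0.8, 0.4, t_switch = 3,
                         gamma_fn = function(t) 0.4 * (1 + 4 * t / 10))
    res3 <- solveTimeDependentKinetics(kin3, tt)
    expect_true(all(res3$s[tt > 1] < res$s[tt > 1]))
})

test_that("trajectories stay nonnegative from nonnegative starts", {
    set.seed(5)
    for (r in 1:5) {
        kin <- geneKinetics(runif(1, 1, 5), runif(1, 0.2, 1),
                            runif(1, 0.1, 0.5), t_switch = runif(1, 2, 8))
        res <- solveConstantKinetics(kin, seq(0, 12, by = 0.1))
        expect_true(all(res$u >= -1e-12) && all(res$s >= -1e-12))
    }
})

test_that("population simulation honours the printed protocol and truth", {
    vs <- simulatePopulation(500, 30, n_reversed = 3, seed = 21)
    expect_identical(dim(vs), c(30L, 500L))
    truth <- simulationTruth(vs)
    expect_identical(sum(truth$kinetics$reversed), 3L)
    expect_true(all(pseudotime(vs) >= 0 & pseudotime(vs) <= truth$t_max))

    # same seed -> bit-identical; different seed -> different
    again <- simulatePopulation(500, 30, n_reversed = 3, seed = 21)
    expect_identical(spliced(vs), spliced(again))
    expect_identical(assay(vs, "true_velocity"), assay(again, "true_velocity"))
    other <- simulatePopulation(500, 30, n_reversed = 3, seed = 22)
    expect_false(identical(spliced(vs), spliced(other)))

    expect_error(simulatePopulation(0, 5), "positive")
    expect_error(simulatePopulation(10, 5, n_reversed = 9), "n_reversed")
})

test_that("noise-free observations equal the integrated trajectories and
           true velocity matches a finite difference of s(t)", {
    vs <- simulatePopulation(40, 4, noise_sd = 0, seed = 8)
    truth <- simulationTruth(vs)
    kin <- truth$kinetics
    tt <- pseudotime(vs)
    for (g in 1:4) {
        k <- geneKinetics(kin$alpha[g], kin$beta[g], kin$gamma[g],
                          t_switch = kin$t_switch[g])
        o <- order(tt)
        res <- solveConstantKinetics(k, tt[o])
        expect_equal(unname(spliced(vs)[g, o]), res$s, tolerance = 1e-10)
        expect_equal(unname(unspliced(vs)[g, o]), res$u, tolerance = 1e-10)
        # O(dt^2) central difference around each cell's time
        h <- 1e-4
        for (i in sample(seq_along(tt), 5)) {
            pair <- solveConstantKinetics(k, sort(c(tt[i] - h, tt[i] + h)))
            expect_equal(unname(assay(vs, "true_velocity")[g, i]),
                         diff(pair$s) / (2 * h), tolerance = 1e-6)
        }
    }
})

test_that("sufficiently increasing gamma(t) reverses the phase-portrait
           loop orientation", {
    # orientation measured as the signed (shoelace) area of the (s, u)
    # trajectory; constant rates trace one orientation, a sufficiently
    # increasing degradation rate flips it, and the default linear schedule
    # already shrinks the loop towards the flip
    shoelace <- function(res)
        0.5 * sum(res$s * c(res$u[-1], res$u[1]) -
                  c(res$s[-1], res$s[1]) * res$u)
    tt <- seq(0, 10, by = 0.02)
    base <- geneKinetics(4, 0.8, 0.25, t_switch = 4)
    a_const <- shoelace(solveConstantKinetics(base, tt))
    mild <- geneKinetics(4, 0.8, 0.25, t_switch = 4,
                         gamma_fn = function(t) 0.25 * (1 + 4 * t / 10))
    a_mild <- shoelace(solveTimeDependentKinetics(mild, tt))
    strong <- geneKinetics(4, 0.8, 0.25, t_switch = 4,
                           gamma_fn = function(t) 0.25 * (1 + 40 * t / 10))
    a_strong <- shoelace(solveTimeDependentKinetics(strong, tt))
    expect_lt(abs(a_mild), abs(a_const))                 # partial reversal
    expect_true(sign(a_strong) != sign(a_const))         # full reversal
})

test_that("two-regime simulation gives opposite true velocity signs", {
    kin_a <- geneKinetics(3, 0.6, 0.3, t_switch = Inf)          # induction
    kin_b <- geneKinetics(3, 0.6, 0.3, t_switch = 0,
                          u0 = 5, s0 = 10)                      # repression
    vs <- simulateTwoRegimeGene(60, kin_a, kin_b, seed = 4)
    lin <- colData(vs)$lineage
    tv <- assay(vs, "true_velocity")["focal", ]
    expect_gt(mean(tv[lin == "A"]), 0)
    expect_lt(mean(tv[lin == "B"]), 0)

    # identical kinetics -> lineages statistically indistinguishable
    vs2 <- simulateTwoRegimeGene(100, kin_a, kin_a, seed = 4, noise_sd = 0.05)
    lin2 <- colData(vs2)$lineage
    sa <- spliced(vs2)["focal", lin2 == "A"]
    sb <- spliced(vs2)["focal", lin2 == "B"]
    expect_gt(suppressWarnings(ks.test(sa, sb))$p.value, 0.01)

    # determinism
    vs3 <- simulateTwoRegimeGene(60, kin_a, kin_b, seed = 4)
    expect_identical(spliced(vs), spliced(vs3))
})
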