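#' Per-gene splicing kinetics
#'
#' Parameters of the two-equation splicing ODE
#' du/dt = alpha(t) - beta u, ds/dt = beta u - gamma(t) s.
#' Transcription runs at rate \code{alpha} until \code{t_switch} and is off
#' afterwards. \code{gamma_fn}, when given, makes the degradation rate
#' time-dependent; otherwise gamma is the constant \code{gamma}.
#'
#' @param alpha transcription rate (>= 0, molecules per unit time).
#' @param beta splicing rate (> 0, 1/time).
#' @param gamma degradation rate (> 0, 1/time) or the value gamma_fn(0).
#' @param t_switch time at which transcription turns off (default Inf: never).
#' @param gamma_fn optional function of time returning gamma(t) > 0.
#' @param u0,s0 initial unspliced/spliced abundance (default 0).
#' @param regime_label optional lineage tag.
#' @return a list of class \code{gene_kinetics}.
#' @export
geneKinetics <- function(alpha, beta, gamma, t_switch = Inf, gamma_fn = NULL,
                         u0 = 0, s0 = 0, regime_label = NULL) {
    if (beta <= 0) stop("beta must be > 0")
    if (is.null(gamma_fn) && gamma <= 0) stop("gamma must be > 0")
    if (t_switch < 0) stop("t_switch must be >= 0")
    structure(list(alpha = alpha, beta = beta, gamma = gamma,
                   t_switch = t_switch, gamma_fn = gamma_fn,
                   u0 = u0, s0 = s0, regime_label = regime_label),
              class = "gene_kinetics")
}

# closed-form solution with constant alpha over [0, t]
.solve_const_piece <- function(alpha, beta, gamma, t, u0, s0) {
    eb <- exp(-beta * t)
    eg <- exp(-gamma * t)
    u <- alpha / beta + (u0 - alpha / beta) * eb
    if (abs(gamma - beta) < 1e-9) {
        # degenerate limit: repeated exponential
        s <- alpha / gamma + (s0 - alpha / gamma) * eg +
            (beta * u0 - alpha) * t * eb
    } else {
        s <- alpha / gamma + (s0 - alpha / gamma) * eg +
            (beta * u0 - alpha) / (gamma - beta) * (eb - eg)
    }
    list(u = u, s = s)
}

#' Closed-form trajectories under constant rates
#'
#' Exact solution of the splicing ODE with constant beta and gamma;
#' transcription at rate alpha until \code{t_switch}, zero afterwards
#' (continuing from the switch-time state).
#'
#' @param kin a \code{\link{geneKinetics}} with constant gamma.
#' @param t nondecreasing time vector.
#' @param u0,s0 initial conditions; default taken from \code{kin}.
#' @return list with vectors \code{u}, \code{s}, and \code{v = ds/dt}.
#' @export
solveConstantKinetics <- function(kin, t, u0 = kin$u0, s0 = kin$s0) {
    if (kin$beta <= 0 || kin$gamma <= 0) stop("beta and gamma must be > 0")
    if (is.unsorted(t)) stop("t must be nondecreasing")
    on <- t <= kin$t_switch
    u <- s <- numeric(length(t))
    if (any(on)) {
        res <- .solve_const_piece(kin$alpha, kin$beta, kin$gamma, t[on], u0, s0)
        u[on] <- res$u
        s[on] <- res$s
    }
    if (any(!on)) {
        sw <- .solve_const_piece(kin$alpha, kin$beta, kin$gamma,
                                 kin$t_switch, u0, s0)
        res <- .solve_const_piece(0, kin$beta, kin$gamma,
                                  t[!on] - kin$t_switch, sw$u, sw$s)
        u[!on] <- res$u
        s[!on] <- res$s
    }
    list(u = u, s = s, v = kin$beta * u - kin$gamma * s)
}

#' Numerical trajectories under time-dependent degradation
#'
#' Adaptive numerical integration (lsoda) of the splicing ODE with a
#' time-dependent gamma(t). For constant gamma this agrees with
#' \code{\link{solveConstantKinetics}} to high accuracy.
#'
#' @param kin a \code{\link{geneKinetics}}; \code{gamma_fn} used if present.
#' @param t nondecreasing time vector (first entry is the initial time).
#' @param u0,s0 initial conditions at \code{t[1]}.
#' @return list with vectors \code{u}, \code{s}, \code{v = ds/dt}.
#' @export
solveTimeDependentKinetics <- function(kin, t, u0 = kin$u0, s0 = kin$s0) {
    if (is.unsorted(t)) stop("t must be nondecreasing")
    gfn <- if (is.null(kin$gamma_fn)) function(tt) kin$gamma else kin$gamma_fn
    rhs <- function(tt, y, parms) {
        a <- if (tt <= kin$t_switch) kin$alpha else 0
        g <- gfn(tt)
        list(c(a - kin$beta * y[1], kin$beta * y[1] - g * y[2]))
    }
    tt <- t
    single <- length(tt) == 1L
    if (single) tt <- c(tt, tt + 1e-8)
    out <- deSolve::ode(y = c(u = u0, s = s0), times = tt, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-10)
    if (attr(out, "istate")[1] < 0)
        stop(sprintf("integration failed near t = %g", utils::tail(out[, 1], 1)))
    u <- out[seq_along(t), "u"]
    s <- out[seq_along(t), "s"]
    g <- vapply(t, gfn, numeric(1))
    list(u = u, s = s, v = kin$beta * u - g * s)
}

# draw a log-uniform value
.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# evaluate one gene's trajectory at (unsorted) cell times
.gene_states <- function(kin, times) {
    if (is.null(kin$gamma_fn)) {
        o <- order(times)
        res <- solveConstantKinetics(kin, times[o])
        u <- s <- v <- numeric(length(times))
        u[o] <- res$u; s[o] <- res$s; v[o] <- res$v
    } else {
        o <- order(times)
        tt <- times[o]
        t0 <- min(0, tt[1])
        res <- solveTimeDependentKinetics(kin, c(t0, tt))
        u <- s <- v <- numeric(length(times))
        u[o] <- res$u[-1]; s[o] <- res$s[-1]; v[o] <- res$v[-1]
    }
    list(u = u, s = s, v = v)
}

.apply_noise <- function(m, noise_sd, model) {
    if (noise_sd <= 0 && model == "lognormal") return(m)
    switch(model,
        lognormal = m * matrix(exp(stats::rnorm(length(m), 0, noise_sd)),
                               nrow(m)),
        poisson = matrix(stats::rpois(length(m), lambda = m), nrow(m)),
        stop("unknown noise model"))
}

#' Simulate a cell population with known kinetics
#'
#' Cells receive pseudotimes uniform on [0, t_max]; each gene follows the
#' splicing ODE with rates drawn log-uniformly (alpha in [1,5], beta in
#' [0.2,1], gamma in [0.1,0.5]) and a transcription switch-off time uniform
#' on [0.3, 0.7] t_max. \code{n_reversed} genes get a degradation rate
#' increasing over time, gamma(t) = gamma0 (1 + 4 t / t_max), which reverses
#' their late phase-portrait trajectory. Observed layers get multiplicative
#' log-normal noise (or Poisson sampling); the stored true velocity is
#' noise-free.
#'
#' @param n_cells,n_genes population dimensions.
#' @param n_reversed number of genes with increasing gamma(t).
#' @param noise_sd log-normal noise sd (default 0.1).
#' @param seed RNG seed.
#' @param t_max simulation horizon (default 10 time units).
#' @param kinetics optional list of \code{\link{geneKinetics}} overriding the
#'   random draw (length \code{n_genes}).
#' @param noise_model \code{"lognormal"} or \code{"poisson"}.
#' @return a \linkS4class{VeloSet} with colData \code{pseudotime} and
#'   \code{lineage}, assay \code{"true_velocity"}, and the full ground truth
#'   in \code{\link{simulationTruth}}.
#' @export
simulatePopulation <- function(n_cells = 500L, n_genes = 30L, n_reversed = 0L,
                               noise_sd = 0.1, seed = 1L, t_max = 10,
                               kinetics = NULL,
                               noise_model = c("lognormal", "poisson")) {
    if (n_cells < 1 || n_genes < 1) stop("dimensions must be positive")
    if (n_reversed > n_genes) stop("n_reversed must be <= n_genes")
    noise_model <- match.arg(noise_model)
    set.seed(seed)
    times <- stats::runif(n_cells, 0, t_max)
    if (is.null(kinetics)) {
        alpha <- .runif_log(n_genes, 1, 5)
        beta <- .runif_log(n_genes, 0.2, 1)
        gamma0 <- .runif_log(n_genes, 0.1, 0.5)
        ts <- stats::runif(n_genes, 0.3 * t_max, 0.7 * t_max)
        reversed <- seq_len(n_genes) <= n_reversed
        kinetics <- lapply(seq_len(n_genes), function(g) {
            gfn <- if (reversed[g]) {
                local({ g0 <- gamma0[g]; function(tt) g0 * (1 + 4 * tt / t_max) })
            } else NULL
            geneKinetics(alpha[g], beta[g], gamma0[g], t_switch = ts[g],
                         gamma_fn = gfn)
        })
    } else {
        stopifnot(length(kinetics) == n_genes)
        reversed <- vapply(kinetics, function(k) !is.null(k$gamma_fn), logical(1))
    }
    u <- s <- v <- matrix(0, n_genes, n_cells)
    for (g in seq_len(n_genes)) {
        st <- .gene_states(kinetics[[g]], times)
        u[g, ] <- st$u; s[g, ] <- st$s; v[g, ] <- st$v
    }
    u_obs <- pmax(.apply_noise(u, noise_sd, noise_model), 0)
    s_obs <- pmax(.apply_noise(s, noise_sd, noise_model), 0)
    kin_df <- data.frame(
        gene = sprintf("gene_%d", seq_len(n_genes)),
        alpha = vapply(kinetics, `[[`, numeric(1), "alpha"),
        beta = vapply(kinetics, `[[`, numeric(1), "beta"),
        gamma = vapply(kinetics, `[[`, numeric(1), "gamma"),
        t_switch = vapply(kinetics, `[[`, numeric(1), "t_switch"),
        reversed = reversed)
    lineage <- rep("main", n_cells)
    vs <- VeloSet(spliced = s_obs, unspliced = u_obs,
                  pseudotime = times, lineage = lineage)
    assay(vs, "true_velocity") <- `dimnames<-`(v, dimnames(spliced(vs)))
    metadata(vs)$simulation_truth <- list(
        pseudotime = times, true_velocity = assay(vs, "true_velocity"),
        kinetics = kin_df, kinetics_list = kinetics,
        lineage = lineage, seed = seed, t_max = t_max, noise_sd = noise_sd)
    vs
}

#' Simulate a gene governed by two kinetic regimes
#'
#' Two lineage-labelled cell groups share one focal gene (gene 1) that
#' follows different kinetics in each regime -- the multi-trajectory
#' phase-portrait scenario. \code{n_background} further genes follow a
#' common randomly drawn constant-rate kinetics in both regimes, giving the
#' model a multi-gene expression space.
#'
#' @param n_cells_per_regime cells per lineage.
#' @param kin_a,kin_b \code{\link{geneKinetics}} of the focal gene in
#'   lineages A and B.
#' @param seed RNG seed.
#' @param n_background number of shared-kinetics background genes.
#' @param t_max simulation horizon.
#' @param noise_sd log-normal noise sd.
#' @return a \linkS4class{VeloSet} with colData \code{lineage} ("A"/"B"),
#'   focal gene named \code{"focal"}; ground truth via
#'   \code{\link{simulationTruth}}.
#' @export
simulateTwoRegimeGene <- function(n_cells_per_regime = 150L, kin_a, kin_b,
                                  seed = 1L, n_background = 10L, t_max = 10,
                                  noise_sd = 0.05) {
    set.seed(seed)
    n <- 2L * n_cells_per_regime
    lineage <- rep(c("A", "B"), each = n_cells_per_regime)
    times <- stats::runif(n, 0, t_max)
    bg <- lapply(seq_len(n_background), function(g)
        geneKinetics(.runif_log(1, 1, 5), .runif_log(1, 0.2, 1),
                     .runif_log(1, 0.1, 0.5),
                     t_switch = stats::runif(1, 0.3 * t_max, 0.7 * t_max)))
    d <- n_background + 1L
    u <- s <- v <- matrix(0, d, n)
    ia <- lineage == "A"
    sta <- .gene_states(kin_a, times[ia])
    stb <- .gene_states(kin_b, times[!ia])
    u[1, ia] <- sta$u; s[1, ia] <- sta$s; v[1, ia] <- sta$v
    u[1, !ia] <- stb$u; s[1, !ia] <- stb$s; v[1, !ia] <- stb$v
    for (g in seq_len(n_background)) {
        st <- .gene_states(bg[[g]], times)
        u[g + 1L, ] <- st$u; s[g + 1L, ] <- st$s; v[g + 1L, ] <- st$v
    }
    u_obs <- pmax(.apply_noise(u, noise_sd, "lognormal"), 0)
    s_obs <- pmax(.apply_noise(s, noise_sd, "lognormal"), 0)
    rownames(u_obs) <- rownames(s_obs) <-
        c("focal", sprintf("bg_%d", seq_len(n_background)))
    vs <- VeloSet(spliced = s_obs, unspliced = u_obs,
                  pseudotime = times, lineage = lineage,
                  cell_type = lineage)
    assay(vs, "true_velocity") <- `dimnames<-`(v, dimnames(spliced(vs)))
    metadata(vs)$simulation_truth <- list(
        pseudotime = times, true_velocity = assay(vs, "true_velocity"),
        kinetics = list(focal_a = kin_a, focal_b = kin_b, background = bg),
        lineage = lineage, seed = seed, t_max = t_max, noise_sd = noise_sd)
    vs
}
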