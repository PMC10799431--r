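#' Training-objective configuration
#'
#' Weights and optimization settings of the continuity objective: forward and
#' backward extrapolation terms and the Pearson direction regularizer,
#' combined as w_f * L+ + w_b * L- + w_p * L_Pearson (defaults 1, 1, 18),
#' minimized with Adam (AMSGrad) at learning rate 0.001 decayed by 0.97 per
#' epoch, full-size batches, 100 epochs.
#'
#' @param k_candidates candidate neighbourhood size (default 30; the
#'   preprocessing kNN graph is reused).
#' @param weight_forward,weight_backward,weight_pearson loss term weights.
#' @param lambda_u,lambda_s scale factors inside the Pearson term.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param batch_size only \code{"full"} (full-size batch) is supported.
#' @return a list of class \code{objective_config}.
#' @export
objectiveConfig <- function(k_candidates = 30L, weight_forward = 1.0,
                            weight_backward = 1.0, weight_pearson = 18.0,
                            lambda_u = 1.0, lambda_s = 1.0, epochs = 100L,
                            learning_rate = 0.001, lr_decay = 0.97,
                            batch_size = "full") {
    stopifnot(weight_forward >= 0, weight_backward >= 0, weight_pearson >= 0,
              epochs >= 1, learning_rate >= 0, identical(batch_size, "full"))
    structure(list(k_candidates = as.integer(k_candidates),
                   weight_forward = weight_forward,
                   weight_backward = weight_backward,
                   weight_pearson = weight_pearson,
                   lambda_u = lambda_u, lambda_s = lambda_s,
                   epochs = as.integer(epochs),
                   learning_rate = learning_rate, lr_decay = lr_decay,
                   batch_size = batch_size),
              class = "objective_config")
}

# candidate probabilities on cells x genes matrices.
# S: cells x genes smoothed spliced; idx: N x k neighbour indices;
# V: cells x genes velocity; sgn: +1 forward, -1 backward.
.target_probs <- function(S, idx, V, sgn) {
    n <- nrow(S)
    k <- ncol(idx)
    sv <- rowSums(S * V)
    vnorm2 <- rowSums(V * V)
    pos <- matrix(FALSE, n, k)
    for (c in seq_len(k)) {
        dot <- rowSums(S[idx[, c], , drop = FALSE] * V) - sv
        pos[, c] <- (sgn * dot) > 0
    }
    pos[vnorm2 == 0, ] <- FALSE
    z <- rowSums(pos)
    prob <- pos / pmax(z, 1L)
    list(prob = prob, z = as.integer(z))
}

#' Candidate target / source distributions
#'
#' For each cell, places uniform probability 1/Z on the neighbour candidates
#' whose expression displacement s_j - s_i has strictly positive cosine with
#' the cell's velocity (forward) or its negation (backward), and zero
#' elsewhere. Z counts the positive-cosine candidates; zero-velocity cells
#' (or cells with no aligned candidate) get an all-zero row.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param graph a \linkS4class{NeighborGraph} providing the candidates.
#' @param velocity a \linkS4class{VelocityEstimate} (or genes x cells matrix).
#' @param direction \code{"forward"} or \code{"backward"}.
#' @return a \linkS4class{TargetDistribution}.
#' @export
candidateTargetProbabilities <- function(x, graph, velocity,
                                         direction = c("forward", "backward")) {
    direction <- match.arg(direction)
    v <- if (is(velocity, "VelocityEstimate")) velocity@v else velocity
    S <- t(as.matrix(splicedSmooth(x)))
    V <- t(as.matrix(v))
    tp <- .target_probs(S, graph@index, V,
                        if (direction == "forward") 1 else -1)
    new("TargetDistribution", candidates = graph@index, prob = tp$prob,
        z = tp$z, direction = direction)
}

# probability-weighted candidate expression, cells x genes
.weighted_targets <- function(S, idx, prob) {
    n <- nrow(S)
    nz <- which(prob > 0, arr.ind = TRUE)
    P <- sparseMatrix(i = nz[, 1], j = idx[nz], x = prob[nz], dims = c(n, n))
    as.matrix(P %*% S)
}

#' Continuity (extrapolation) loss
#'
#' Mean squared deviation between the extrapolated state s_i + v_i (forward)
#' or s_i - v_i (backward) and the probability-weighted expression of the
#' candidate cells, averaged over genes and over the cells with a nonempty
#' candidate set (Z > 0); empty cells contribute nothing.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param velocity a \linkS4class{VelocityEstimate} (or genes x cells matrix).
#' @param targets the matching \linkS4class{TargetDistribution}.
#' @return a nonnegative scalar.
#' @export
continuityLoss <- function(x, velocity, targets) {
    v <- if (is(velocity, "VelocityEstimate")) velocity@v else velocity
    S <- t(as.matrix(splicedSmooth(x)))
    V <- t(as.matrix(v))
    sgn <- if (targets@direction == "forward") 1 else -1
    Tm <- .weighted_targets(S, targets@candidates, targets@prob)
    act <- targets@z > 0L
    if (!any(act)) return(0)
    resid <- (S + sgn * V - Tm)[act, , drop = FALSE]
    sum(resid^2) / (sum(act) * ncol(S))
}

# per-gene Pearson terms and (optionally) gradients wrt V.
# V, U, S: cells x genes. Returns value of
#   -(lambda_u * mean_valid corr(v, u) + lambda_s * mean_valid corr(v, -s))
.pearson_terms <- function(V, U, S, lambda_u, lambda_s, grad = FALSE) {
    n <- nrow(V)
    Vc <- sweep(V, 2, colMeans(V))
    Uc <- sweep(U, 2, colMeans(U))
    Sc <- sweep(S, 2, colMeans(S))
    vv <- colSums(Vc^2)
    uu <- colSums(Uc^2)
    ss <- colSums(Sc^2)
    tol <- 1e-12
    valid_u <- vv > tol & uu > tol
    valid_s <- vv > tol & ss > tol
    corr_u <- ifelse(valid_u, colSums(Vc * Uc) / sqrt(vv * uu), 0)
    corr_s <- ifelse(valid_s, colSums(Vc * (-Sc)) / sqrt(vv * ss), 0)
    mu <- if (any(valid_u)) sum(corr_u[valid_u]) / sum(valid_u) else 0
    ms <- if (any(valid_s)) sum(corr_s[valid_s]) / sum(valid_s) else 0
    out <- list(value = -(lambda_u * mu + lambda_s * ms),
                corr_u = corr_u, corr_s = corr_s,
                valid_u = valid_u, valid_s = valid_s)
    if (grad) {
        G <- matrix(0, n, ncol(V))
        if (any(valid_u)) {
            ju <- which(valid_u)
            den <- sqrt(vv[ju] * uu[ju])
            Gu <- sweep(Uc[, ju, drop = FALSE], 2, den, "/") -
                sweep(Vc[, ju, drop = FALSE], 2, corr_u[ju] / vv[ju], "*")
            G[, ju] <- G[, ju] - (lambda_u / sum(valid_u)) * Gu
        }
        if (any(valid_s)) {
            js <- which(valid_s)
            den <- sqrt(vv[js] * ss[js])
            Gs <- sweep(-Sc[, js, drop = FALSE], 2, den, "/") -
                sweep(Vc[, js, drop = FALSE], 2, corr_s[js] / vv[js], "*")
            G[, js] <- G[, js] - (lambda_s / sum(valid_s)) * Gs
        }
        out$grad <- G
    }
    out
}

#' Pearson direction regularizer
#'
#' Per-gene Pearson correlation (across cells) of the velocity with the
#' unspliced layer and with the negated spliced layer, each averaged over the
#' genes where both arguments have nonzero variance; returns the negated
#' weighted sum. Drives velocities to be positive where unspliced expression
#' is high and negative where spliced expression is high, breaking the sign
#' symmetry of the extrapolation terms.
#'
#' @param velocity a \linkS4class{VelocityEstimate} (or genes x cells matrix).
#' @param x a preprocessed \linkS4class{VeloSet} (>= 2 cells).
#' @param lambda_u,lambda_s term weights.
#' @return a scalar (negative when the heuristic holds).
#' @export
pearsonLoss <- function(velocity, x, lambda_u = 1.0, lambda_s = 1.0) {
    if (ncol(x) < 2) stop("pearsonLoss needs at least 2 cells")
    v <- if (is(velocity, "VelocityEstimate")) velocity@v else velocity
    .pearson_terms(t(as.matrix(v)), t(as.matrix(unsplicedSmooth(x))),
                   t(as.matrix(splicedSmooth(x))),
                   lambda_u, lambda_s)$value
}

#' Combined continuity objective
#'
#' Recomputes the forward/backward target distributions from the given
#' velocity and returns all loss components together with
#' total = w_f * L+ + w_b * L- + w_p * L_Pearson.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param velocity a \linkS4class{VelocityEstimate} (or genes x cells matrix).
#' @param config an \code{\link{objectiveConfig}}.
#' @return a list of class \code{loss_breakdown} with elements
#'   \code{loss_forward}, \code{loss_backward}, \code{loss_pearson},
#'   \code{total}.
#' @export
totalLoss <- function(x, graph, velocity, config = objectiveConfig()) {
    tf <- candidateTargetProbabilities(x, graph, velocity, "forward")
    tb <- candidateTargetProbabilities(x, graph, velocity, "backward")
    lf <- continuityLoss(x, velocity, tf)
    lb <- continuityLoss(x, velocity, tb)
    lp <- pearsonLoss(velocity, x, config$lambda_u, config$lambda_s)
    structure(list(loss_forward = lf, loss_backward = lb, loss_pearson = lp,
                   total = config$weight_forward * lf +
                       config$weight_backward * lb +
                       config$weight_pearson * lp),
              class = "loss_breakdown")
}

# Adam with AMSGrad, one step over a named list of gradients
.adam_step <- function(par, grads, state, lr, step,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
    for (nm in names(grads)) {
        g <- grads[[nm]]
        state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
        state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
        state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
        denom <- sqrt(state$vhat[[nm]] / (1 - b2^step)) + eps
        par[[nm]] <- par[[nm]] - lr / (1 - b1^step) * state$m[[nm]] / denom
    }
    list(par = par, state = state)
}

# loss + full gradient wrt all trainable weights, one full-batch pass.
# Target probabilities are treated as constants (no gradient), recomputed
# from the current training-mode velocity.
.loss_and_grads <- function(model, X, S, U, idx, cfg, training = TRUE) {
    fw <- .gcn_forward(model, X, training = training)
    V <- fw$beta * U - fw$gamma * S
    n <- nrow(S); d <- ncol(S)

    tpf <- .target_probs(S, idx, V, 1)
    tpb <- .target_probs(S, idx, V, -1)
    Tf <- .weighted_targets(S, idx, tpf$prob)
    Tb <- .weighted_targets(S, idx, tpb$prob)
    af <- tpf$z > 0L
    ab <- tpb$z > 0L
    dV <- matrix(0, n, d)
    if (any(af)) {
        Rf <- S + V - Tf
        Rf[!af, ] <- 0
        lf <- sum(Rf^2) / (sum(af) * d)
        dV <- dV + cfg$weight_forward * 2 * Rf / (sum(af) * d)
    } else lf <- 0
    if (any(ab)) {
        Rb <- S - V - Tb
        Rb[!ab, ] <- 0
        lb <- sum(Rb^2) / (sum(ab) * d)
        dV <- dV - cfg$weight_backward * 2 * Rb / (sum(ab) * d)
    } else lb <- 0
    pt <- .pearson_terms(V, U, S, cfg$lambda_u, cfg$lambda_s, grad = TRUE)
    lp <- pt$value
    dV <- dV + cfg$weight_pearson * pt$grad

    # velocity -> rate blocks
    dRates <- matrix(0, n, model@config$n_blocks * d)
    dRates[, seq_len(d)] <- dV * U
    dRates[, d + seq_len(d)] <- -dV * S
    dZout <- dRates * .sigmoid(fw$Zout)

    w <- model@weights
    nh <- length(model@config$hidden_sizes)
    grads <- list()
    H_last <- if (nh > 0) fw$cache$H[[nh]] else X
    grads$W_head <- t(H_last) %*% dZout
    grads$b_head <- colSums(dZout)
    dH <- dZout %*% t(w$W_head)
    A <- model@normAdj
    for (l in rev(seq_len(nh))) {
        if (!is.null(fw$cache$mask[[l]])) dH <- dH * fw$cache$mask[[l]]
        dZ <- dH * (fw$cache$Z[[l]] > 0)
        grads[[paste0("W", l)]] <- t(fw$cache$AH[[l]]) %*% dZ
        if (l > 1) dH <- as.matrix(A %*% dZ) %*% t(w[[paste0("W", l)]])
    }
    list(grads = grads,
         loss = list(loss_forward = lf, loss_backward = lb, loss_pearson = lp,
                     total = cfg$weight_forward * lf +
                         cfg$weight_backward * lb + cfg$weight_pearson * lp),
         empty_forward = sum(!af), empty_backward = sum(!ab))
}

#' Train the GCN velocity model
#'
#' Full-batch training of the rate-predicting GCN under the continuity
#' objective: each epoch recomputes the forward/backward candidate target
#' probabilities from the current velocities (held constant within the
#' step), evaluates w_f L+ + w_b L- + w_p L_Pearson, backpropagates through
#' velocity, rates and graph convolutions, and updates all weights with Adam
#' (AMSGrad) under a multiplicative learning-rate decay.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param graph a \linkS4class{NeighborGraph}; defaults to the stored one.
#' @param model_config a \code{\link{modelConfig}}.
#' @param objective_config an \code{\link{objectiveConfig}}.
#' @param seed integer controlling initialization and dropout; overrides
#'   \code{model_config$seed}.
#' @param verbose print the loss every 10 epochs.
#' @return a list with elements \code{model} (trained
#'   \linkS4class{GcnModel}) and \code{log} (one row per epoch: loss
#'   components, total, learning rate, empty-candidate cell counts).
#' @export
trainVelocityModel <- function(x, graph = neighborGraph(x),
                               model_config = modelConfig(),
                               objective_config = objectiveConfig(),
                               seed = model_config$seed, verbose = FALSE) {
    if (is.null(graph)) stop("no neighbour graph: run preprocess() first")
    model_config$seed <- as.integer(seed)
    model <- initGcnModel(x, graph, model_config)
    set.seed(seed + 1L)
    S <- t(as.matrix(splicedSmooth(x)))
    U <- t(as.matrix(unsplicedSmooth(x)))
    X <- cbind(S, U)
    idx <- graph@index
    cfg <- objective_config
    state <- list(
        m = lapply(model@weights, function(p) p * 0),
        v = lapply(model@weights, function(p) p * 0),
        vhat = lapply(model@weights, function(p) p * 0))
    lr <- cfg$learning_rate
    log <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
        lg <- .loss_and_grads(model, X, S, U, idx, cfg, training = TRUE)
        if (!is.finite(lg$loss$total))
            stop(sprintf(
                "non-finite loss at epoch %d (forward=%g backward=%g pearson=%g)",
                ep, lg$loss$loss_forward, lg$loss$loss_backward,
                lg$loss$loss_pearson))
        upd <- .adam_step(model@weights, lg$grads, state, lr, ep)
        model@weights <- upd$par
        state <- upd$state
        log[[ep]] <- data.frame(epoch = ep,
                                loss_forward = lg$loss$loss_forward,
                                loss_backward = lg$loss$loss_backward,
                                loss_pearson = lg$loss$loss_pearson,
                                total = lg$loss$total, lr = lr,
                                empty_forward = lg$empty_forward,
                                empty_backward = lg$empty_backward)
        if (verbose && (ep %% 10 == 0 || ep == 1))
            message(sprintf("epoch %3d  total %.6g", ep, lg$loss$total))
        lr <- lr * cfg$lr_decay
    }
    list(model = model, log = do.call(rbind, log))
}

#' Estimate velocity with a trained model
#'
#' Evaluation-mode forward pass followed by the velocity computation;
#' results are attached to the dataset as assays \code{"velocity"},
#' \code{"rate_beta"}, \code{"rate_gamma"} (and \code{"rate_alpha"},
#' \code{"velocity_unspliced"} when an alpha head is present).
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param model a trained \linkS4class{GcnModel} (or the list returned by
#'   \code{\link{trainVelocityModel}}).
#' @return \code{x} with velocity and rate assays.
#' @export
estimateVelocity <- function(x, model) {
    if (is.list(model) && !is.null(model$model)) model <- model$model
    rates <- forwardRates(x, model)
    ve <- computeVelocity(rates, x)
    assay(x, "velocity") <- ve@v
    assay(x, "rate_beta") <- rates@beta
    assay(x, "rate_gamma") <- rates@gamma
    if (!is.null(rates@alpha)) {
        assay(x, "rate_alpha") <- rates@alpha
        assay(x, "velocity_unspliced") <- computeUnsplicedVelocity(rates, x)
    }
    metadata(x)$kinetic_rates <- rates
    x
}
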