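#' Model configuration
#'
#' Architecture settings of the rate-predicting graph convolutional network:
#' two hidden graph-convolution layers of size 64 with ReLU activations and
#' dropout 0.2 between them by default; a fully connected head maps the last
#' hidden layer to softplus-activated rate blocks (beta and gamma; alpha
#' optionally).
#'
#' @param hidden_sizes integer vector of hidden layer widths.
#' @param dropout dropout probability in [0, 1), applied between hidden
#'   layers during training only.
#' @param predict_alpha also predict a transcription-rate block.
#' @param rate_activation output nonlinearity ensuring nonnegative rates
#'   (only \code{"softplus"} is implemented).
#' @param seed seed for weight initialization.
#' @return a list of class \code{model_config}.
#' @export
modelConfig <- function(hidden_sizes = c(64L, 64L), dropout = 0.2,
                        predict_alpha = FALSE, rate_activation = "softplus",
                        seed = 1L) {
    stopifnot(all(hidden_sizes > 0), dropout >= 0, dropout < 1,
              identical(rate_activation, "softplus"))
    structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                   predict_alpha = isTRUE(predict_alpha),
                   rate_activation = rate_activation, seed = as.integer(seed)),
              class = "model_config")
}

.relu <- function(x) pmax(x, 0)

.softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Single graph-convolution layer
#'
#' Evaluates sigma(norm_adj \%*\% H \%*\% W), the layer-wise propagation rule
#' of a graph convolutional network, with sigma = ReLU or identity.
#'
#' @param H node features, N x F.
#' @param norm_adj normalized adjacency D^{-1/2} (A + I) D^{-1/2}, N x N.
#' @param W weight matrix, F x F'.
#' @param use_activation apply ReLU.
#' @return node features N x F'.
#' @export
gcnLayerForward <- function(H, norm_adj, W, use_activation = TRUE) {
    if (ncol(H) != nrow(W)) stop("H and W are not conformable")
    if (nrow(H) != ncol(norm_adj)) stop("norm_adj and H are not conformable")
    out <- as.matrix(norm_adj %*% H %*% W)
    if (use_activation) .relu(out) else out
}

.glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize the GCN rate model
#'
#' Builds seeded Glorot-uniform weights for the graph convolution layers and
#' the fully connected rate head, and precomputes the symmetrically
#' normalized adjacency of the neighbour graph.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param graph a \linkS4class{NeighborGraph}; defaults to the one stored by
#'   preprocessing.
#' @param config a \code{\link{modelConfig}}.
#' @return a \linkS4class{GcnModel}.
#' @export
initGcnModel <- function(x, graph = neighborGraph(x), config = modelConfig()) {
    if (is.null(graph)) stop("no neighbour graph: run preprocess() first")
    if (nrow(graph@index) != ncol(x))
        stop("graph and dataset disagree on the number of cells")
    d <- nrow(x)
    in_dim <- 2L * d
    n_blocks <- if (config$predict_alpha) 3L else 2L
    set.seed(config$seed)
    dims <- c(in_dim, config$hidden_sizes)
    weights <- list()
    for (l in seq_along(config$hidden_sizes))
        weights[[paste0("W", l)]] <- .glorot(dims[l], dims[l + 1])
    last <- utils::tail(dims, 1)
    weights$W_head <- .glorot(last, n_blocks * d)
    weights$b_head <- numeric(n_blocks * d)
    new("GcnModel", weights = weights, normAdj = normalizedAdjacency(graph),
        config = c(unclass(config),
                   list(n_genes = d, n_blocks = n_blocks)))
}

# full forward pass; cells x genes convention internally.
# Returns caches needed for backpropagation. dropout masks are drawn from the
# current RNG stream when training = TRUE.
.gcn_forward <- function(model, X, training = FALSE) {
    w <- model@weights
    cfg <- model@config
    A <- model@normAdj
    n_hidden <- length(cfg$hidden_sizes)
    H <- X
    cache <- list(AH = list(), Z = list(), H = list(), mask = list())
    for (l in seq_len(n_hidden)) {
        AH <- as.matrix(A %*% H)
        Z <- AH %*% w[[paste0("W", l)]]
        Hl <- .relu(Z)
        mask <- NULL
        if (training && cfg$dropout > 0 && l < n_hidden) {
            mask <- matrix(stats::runif(length(Hl)) >= cfg$dropout,
                           nrow(Hl)) / (1 - cfg$dropout)
            Hl <- Hl * mask
        }
        cache$AH[[l]] <- AH
        cache$Z[[l]] <- Z
        cache$H[[l]] <- Hl
        cache$mask[l] <- list(mask)   # keep NULL placeholders
        H <- Hl
    }
    Zout <- H %*% w$W_head + matrix(w$b_head, nrow(H), length(w$b_head),
                                    byrow = TRUE)
    rates <- .softplus(Zout)
    d <- cfg$n_genes
    out <- list(Zout = Zout, rates = rates, cache = cache,
                beta = rates[, seq_len(d), drop = FALSE],
                gamma = rates[, d + seq_len(d), drop = FALSE])
    if (cfg$n_blocks == 3L)
        out$alpha <- rates[, 2L * d + seq_len(d), drop = FALSE]
    out
}

#' Predict kinetic rates for every cell and gene
#'
#' Runs the GCN forward pass in evaluation mode (dropout off) on the
#' smoothed spliced/unspliced layers and returns softplus-activated,
#' nonnegative per-cell per-gene rates.
#'
#' @param x a preprocessed \linkS4class{VeloSet}.
#' @param model a \linkS4class{GcnModel}.
#' @return a \linkS4class{KineticRates} (genes x cells).
#' @export
forwardRates <- function(x, model) {
    if (model@config$n_genes != nrow(x))
        stop("model and dataset disagree on the number of genes")
    if (ncol(model@normAdj) != ncol(x))
        stop("model and dataset disagree on the number of cells")
    X <- cbind(t(as.matrix(splicedSmooth(x))), t(as.matrix(unsplicedSmooth(x))))
    fw <- .gcn_forward(model, X, training = FALSE)
    dn <- dimnames(spliced(x))
    new("KineticRates",
        alpha = if (is.null(fw$alpha)) NULL else `dimnames<-`(t(fw$alpha), dn),
        beta = `dimnames<-`(t(fw$beta), dn),
        gamma = `dimnames<-`(t(fw$gamma), dn))
}

#' Spliced RNA velocity from kinetic rates
#'
#' v = beta * u - gamma * s, elementwise on the smoothed layers.
#'
#' @param rates a \linkS4class{KineticRates}.
#' @param x the matching preprocessed \linkS4class{VeloSet}.
#' @return a \linkS4class{VelocityEstimate}.
#' @export
computeVelocity <- function(rates, x) {
    u <- as.matrix(unsplicedSmooth(x))
    s <- as.matrix(splicedSmooth(x))
    if (!identical(dim(rates@beta), dim(s)))
        stop("rates and dataset shapes differ")
    new("VelocityEstimate", v = rates@beta * u - rates@gamma * s, vUns = NULL)
}

#' Unspliced RNA derivative from kinetic rates
#'
#' By default the first ODE line, v_uns = alpha - beta * u. The
#' \code{paper_literal} switch instead evaluates alpha - beta * s, the form
#' some descriptions print; the default is the internally consistent one.
#'
#' @param rates a \linkS4class{KineticRates} with an alpha component.
#' @param x the matching preprocessed \linkS4class{VeloSet}.
#' @param paper_literal use alpha - beta * s.
#' @return genes x cells matrix of unspliced derivatives.
#' @export
computeUnsplicedVelocity <- function(rates, x, paper_literal = FALSE) {
    if (is.null(rates@alpha))
        stop("model trained without alpha head")
    if (paper_literal)
        rates@alpha - rates@beta * as.matrix(splicedSmooth(x))
    else
        rates@alpha - rates@beta * as.matrix(unsplicedSmooth(x))
}
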