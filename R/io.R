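# ---- HDF5 bridge -----------------------------------------------------------
# H5AD and Loom are HDF5 containers; they are read/written through the
# bundled python helper (anndata / h5py), exchanging float64 binaries so
# numeric payloads round-trip bit-identically.

.python_bin <- function() {
    py <- Sys.which("python")
    if (py == "") py <- Sys.which("python3")
    if (py == "") stop("no 'python' interpreter found on PATH; ",
                       "H5AD/Loom support requires one (with anndata/h5py)")
    py
}

.bridge_script <- function() {
    p <- system.file("python", "h5ad_bridge.py", package = "velogcn")
    if (p == "") stop("bundled python bridge not found")
    p
}

.run_bridge <- function(args) {
    out <- suppressWarnings(system2(.python_bin(),
                                    c(.bridge_script(), args),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
        stop("python bridge failed:\n", paste(out, collapse = "\n"))
    invisible(out)
}

.read_bin_mat <- function(path, n_row, n_col) {
    v <- readBin(path, what = "double", n = n_row * n_col, size = 8)
    matrix(v, n_row, n_col)
}

.write_bin_mat <- function(path, m) {
    writeBin(as.vector(as.matrix(m)), path, size = 8)
}

# read an exchange directory written by the bridge into a VeloSet
.read_exchange <- function(dir, layer_names) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    avail <- meta$layers
    for (role in c("spliced", "unspliced")) {
        if (!layer_names[[role]] %in% avail)
            stop(sprintf("%s layer '%s' missing; available layers: %s",
                         role, layer_names[[role]],
                         paste(avail, collapse = ", ")))
    }
    ng <- meta$n_genes; nc <- meta$n_cells
    lay <- function(name)
        .read_bin_mat(file.path(dir, "layers", paste0(name, ".bin")), ng, nc)
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- readLines(file.path(dir, "cells.tsv"))
    s <- lay(layer_names[["spliced"]])
    u <- lay(layer_names[["unspliced"]])
    dimnames(s) <- dimnames(u) <- list(genes, cells)
    obs <- list()
    for (col in names(meta$obs)) {
        v <- readLines(file.path(dir, "obs", paste0(col, ".tsv")))
        obs[[col]] <- if (meta$obs[[col]] == "numeric") as.numeric(v) else v
    }
    vs <- VeloSet(spliced = s, unspliced = u,
                  cell_type = obs$cell_type,
                  pseudotime = if (!is.null(obs$pseudotime)) obs$pseudotime
                               else obs$true_pseudotime,
                  lineage = obs$lineage)
    for (col in setdiff(names(obs),
                        c("cell_type", "pseudotime", "true_pseudotime",
                          "lineage")))
        colData(vs)[[col]] <- obs[[col]]
    extra <- setdiff(avail, c(layer_names, "X"))
    for (name in extra) {
        m <- lay(name)
        dimnames(m) <- list(genes, cells)
        assay(vs, name) <- m
    }
    if (length(meta$obsm) > 0) {
        for (name in names(meta$obsm)) {
            m <- t(.read_bin_mat(file.path(dir, "obsm", paste0(name, ".bin")),
                                 meta$obsm[[name]], nc))
            rownames(m) <- cells
            key <- if (name %in% c("X_umap", "X_tsne", "EMBED")) "EMBED"
                   else if (name %in% c("X_pca", "PCA")) "PCA" else name
            reducedDim(vs, key) <- m
        }
    }
    vs
}

# write a VeloSet (all assays, key colData, reducedDims) as an exchange dir
.write_exchange <- function(x, dir) {
    dir.create(file.path(dir, "layers"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "obs"), showWarnings = FALSE)
    dir.create(file.path(dir, "obsm"), showWarnings = FALSE)
    meta <- list(n_genes = nrow(x), n_cells = ncol(x),
                 layers = assayNames(x), obs = list(), obsm = list())
    for (name in assayNames(x))
        .write_bin_mat(file.path(dir, "layers", paste0(name, ".bin")),
                       assay(x, name))
    writeLines(rownames(x), file.path(dir, "genes.tsv"))
    writeLines(colnames(x), file.path(dir, "cells.tsv"))
    for (col in colnames(colData(x))) {
        v <- colData(x)[[col]]
        num <- is.numeric(v)
        meta$obs[[col]] <- if (num) "numeric" else "character"
        writeLines(if (num) sprintf("%.17g", v) else as.character(v),
                   file.path(dir, "obs", paste0(col, ".tsv")))
    }
    for (name in reducedDimNames(x)) {
        m <- reducedDim(x, name)
        key <- if (name == "EMBED") "X_umap" else if (name == "PCA") "X_pca"
               else name
        meta$obsm[[key]] <- ncol(m)
        .write_bin_mat(file.path(dir, "obsm", paste0(key, ".bin")), t(m))
    }
    if (length(meta$obs) == 0) meta$obs <- stats::setNames(list(), character(0))
    if (length(meta$obsm) == 0) meta$obsm <- stats::setNames(list(), character(0))
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

# ---- public readers/writers ------------------------------------------------

#' Load a spliced/unspliced dataset
#'
#' Reads an H5AD or Loom file (through the bundled python bridge) or an MTX
#' directory (\code{spliced.mtx}, \code{unspliced.mtx}, \code{genes.tsv},
#' \code{barcodes.tsv}) into a \linkS4class{VeloSet}. A missing layer raises
#' an error naming the layers that are present.
#'
#' @param path file (h5ad/loom) or directory (mtx_dir).
#' @param format one of \code{"h5ad"}, \code{"loom"}, \code{"mtx_dir"};
#'   guessed from the path when omitted.
#' @param layer_names named character pair mapping roles to stored layer
#'   names, e.g. \code{c(spliced = "spliced", unspliced = "unspliced")}.
#' @return a \linkS4class{VeloSet} with the raw layers preserved.
#' @export
loadDataset <- function(path, format = c("auto", "h5ad", "loom", "mtx_dir"),
                        layer_names = c(spliced = "spliced",
                                        unspliced = "unspliced")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (dir.exists(path)) "mtx_dir"
                  else if (grepl("\\.h5ad$", path)) "h5ad"
                  else if (grepl("\\.loom$", path)) "loom"
                  else stop("cannot guess format of ", path)
    }
    if (!file.exists(path)) stop("no such file or directory: ", path)
    if (format == "mtx_dir") return(.read_mtx_dir(path))
    tmp <- tempfile("bridge_")
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    .run_bridge(c(if (format == "h5ad") "export-h5ad" else "export-loom",
                  shQuote(path), shQuote(tmp)))
    .read_exchange(tmp, as.list(layer_names))
}

.read_mtx_dir <- function(path) {
    sp <- file.path(path, "spliced.mtx")
    up <- file.path(path, "unspliced.mtx")
    have <- basename(Sys.glob(file.path(path, "*.mtx")))
    if (!file.exists(sp))
        stop("spliced layer missing; available: ",
             paste(have, collapse = ", "))
    if (!file.exists(up))
        stop("unspliced layer missing; available: ",
             paste(have, collapse = ", "))
    s <- as.matrix(Matrix::readMM(sp))
    u <- as.matrix(Matrix::readMM(up))
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    genes <- if (file.exists(gf))
        utils::read.table(gf, sep = "\t", stringsAsFactors = FALSE)[, 1]
        else sprintf("gene_%d", seq_len(nrow(s)))
    cells <- if (file.exists(bf))
        utils::read.table(bf, sep = "\t", stringsAsFactors = FALSE)[, 1]
        else sprintf("cell_%d", seq_len(ncol(s)))
    dimnames(s) <- dimnames(u) <- list(genes, cells)
    VeloSet(spliced = s, unspliced = u)
}

#' Write a dataset as an MTX directory
#'
#' @param x a \linkS4class{VeloSet}.
#' @param path output directory (created).
#' @return \code{path}, invisibly.
#' @export
writeMtxDir <- function(x, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(Matrix(as.matrix(spliced(x)), sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "spliced.mtx"))
    Matrix::writeMM(methods::as(Matrix(as.matrix(unspliced(x)), sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "unspliced.mtx"))
    writeLines(rownames(x), file.path(path, "genes.tsv"))
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
    invisible(path)
}

#' Write a VeloSet to H5AD
#'
#' All assays become layers; cell annotation goes to \code{obs}, embeddings
#' to \code{obsm}. Float64 payloads round-trip bit-identically.
#'
#' @param x a \linkS4class{VeloSet}.
#' @param path output .h5ad path.
#' @return \code{path}, invisibly.
#' @export
writeH5ad <- function(x, path) {
    dir <- dirname(path)
    if (!dir.exists(dir) || file.access(dir, 2) != 0)
        stop("cannot write to ", path)
    tmp <- tempfile("bridge_")
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    .write_exchange(x, tmp)
    .run_bridge(c("import-h5ad", shQuote(tmp), shQuote(path)))
    invisible(path)
}

#' Save estimation results to H5AD
#'
#' Attaches the velocity and kinetic-rate matrices to the dataset as layers
#' and writes a single H5AD file.
#'
#' @param x a \linkS4class{VeloSet}.
#' @param rates a \linkS4class{KineticRates} matching \code{x}.
#' @param velocity a \linkS4class{VelocityEstimate} matching \code{x}.
#' @param path output .h5ad path.
#' @return \code{path}, invisibly.
#' @export
saveResults <- function(x, rates, velocity, path) {
    if (!identical(dim(rates@beta), dim(spliced(x))))
        stop("rates shape does not match the dataset")
    if (!identical(dim(velocity@v), dim(spliced(x))))
        stop("velocity shape does not match the dataset")
    dn <- dimnames(spliced(x))
    assay(x, "velocity") <- `dimnames<-`(velocity@v, dn)
    assay(x, "rate_beta") <- `dimnames<-`(rates@beta, dn)
    assay(x, "rate_gamma") <- `dimnames<-`(rates@gamma, dn)
    if (!is.null(rates@alpha))
        assay(x, "rate_alpha") <- `dimnames<-`(rates@alpha, dn)
    if (!is.null(velocity@vUns))
        assay(x, "velocity_unspliced") <- `dimnames<-`(velocity@vUns, dn)
    writeH5ad(x, path)
}

#' Read a run configuration file
#'
#' YAML file mirroring the keys of \code{\link{preprocessConfig}},
#' \code{\link{modelConfig}}, \code{\link{objectiveConfig}} and
#' \code{\link{geneFilterConfig}} under sections \code{preprocess},
#' \code{model}, \code{objective}, \code{gene_filter}, plus optional global
#' \code{seed} and \code{outdir}; missing keys take the defaults.
#'
#' @param path YAML file (NULL for all defaults).
#' @return a list of class \code{run_config} with the four config objects
#'   plus \code{seed} and \code{outdir}.
#' @export
readRunConfig <- function(path = NULL) {
    raw <- if (is.null(path)) list() else yaml::read_yaml(path)
    mk <- function(fn, section) do.call(fn, raw[[section]] %||% list())
    structure(list(preprocess = mk(preprocessConfig, "preprocess"),
                   model = mk(modelConfig, "model"),
                   objective = mk(objectiveConfig, "objective"),
                   gene_filter = mk(geneFilterConfig, "gene_filter"),
                   seed = raw$seed %||% 1L,
                   outdir = raw$outdir %||% "velogcn_out"),
              class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
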