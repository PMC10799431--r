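#' End-to-end pipeline
#'
#' Runs preprocess -> train -> velocity -> metrics -> velocity graph /
#' embedding projection / driver ranking on one dataset, writing every
#' artifact into \code{outdir}: \code{results.h5ad} (layers, rates,
#' velocity), \code{training_log.jsonl}, \code{cell_scores.tsv},
#' \code{gene_scores.tsv}, \code{drivers.tsv}, \code{summary.json} and a
#' \code{manifest.json} recording package version, seed and configuration.
#'
#' @param input path to an input dataset (h5ad/loom/mtx dir) or a
#'   \linkS4class{VeloSet}.
#' @param config a \code{\link{readRunConfig}} list.
#' @param seed global seed (overrides the config seed).
#' @param outdir output directory (overrides the config outdir).
#' @param pairs optional list of cell-type pairs for the direction score.
#' @return (invisibly) a list with the preprocessed dataset, trained model,
#'   training log, metric summary and output paths.
#' @export
runPipeline <- function(input, config = readRunConfig(), seed = config$seed,
                        outdir = config$outdir, pairs = NULL) {
    stage <- "load"
    res <- tryCatch({
        x <- if (is(input, "VeloSet")) input else loadDataset(input)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

        stage <- "preprocess"
        cfg_pp <- config$preprocess
        cfg_pp$n_top_genes <- min(cfg_pp$n_top_genes, nrow(x))
        x <- preprocess(x, cfg_pp)
        graph <- neighborGraph(x)

        stage <- "train"
        fit <- trainVelocityModel(x, graph, config$model, config$objective,
                                  seed = seed)
        log_path <- file.path(outdir, "training_log.jsonl")
        writeLines(vapply(seq_len(nrow(fit$log)), function(i)
            jsonlite::toJSON(as.list(fit$log[i, ]), auto_unbox = TRUE,
                             digits = NA), character(1)), log_path)

        stage <- "velocity"
        x <- estimateVelocity(x, fit$model)
        ve <- new("VelocityEstimate", v = velocity(x), vUns = NULL)

        stage <- "evaluate"
        tfwd <- candidateTargetProbabilities(x, graph, ve, "forward")
        eps <- continuityError(x, ve, tfwd)
        cons <- overallConsistency(ve, graph)
        cs_c <- csCell(eps)
        cs_g <- csGene(eps)
        corr <- correlationScore(ve, x)
        ds <- if (!is.null(pairs) && !is.null(cellType(x)))
            directionScore(x, ve, graph, pairs) else NULL
        utils::write.table(
            data.frame(cell = colnames(x), consistency = cons,
                       cs_cell = cs_c),
            file.path(outdir, "cell_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(gene = rownames(x), cs_gene = cs_g,
                       correlation_score = corr),
            file.path(outdir, "gene_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

        stage <- "graph"
        genes_used <- tryCatch(
            geneConfidenceFilter(x, cs_g, corr, config$gene_filter),
            error = function(e) seq_len(nrow(x)))
        vg <- velocityGraph(x, ve, graph, genes_used)
        Matrix::writeMM(vg@weights, file.path(outdir, "velocity_graph.mtx"))

        stage <- "project"
        arrows <- NULL
        if ("EMBED" %in% reducedDimNames(x)) {
            arrows <- projectVelocity(vg, reducedDim(x, "EMBED"))
            utils::write.table(arrows, file.path(outdir, "arrows.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE,
                               col.names = c("dx", "dy"))
        }

        stage <- "drivers"
        drivers <- NULL
        if (!is.null(pseudotime(x))) {
            drivers <- rankDriverGenes(x, branch_labels = colData(x)$lineage)
            utils::write.table(drivers, file.path(outdir, "drivers.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }

        stage <- "save"
        rates <- metadata(x)$kinetic_rates
        saveResults(x, rates, ve, file.path(outdir, "results.h5ad"))
        summary <- list(
            n_cells = ncol(x), n_genes = nrow(x),
            final_loss = fit$log$total[nrow(fit$log)],
            initial_loss = fit$log$total[1],
            median_consistency = stats::median(cons, na.rm = TRUE),
            median_cs_cell = stats::median(cs_c),
            median_cs_gene = stats::median(cs_g),
            direction_score = if (is.null(ds)) NULL else ds$global,
            genes_used = length(genes_used))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest <- list(
            package = "velogcn",
            version = as.character(utils::packageVersion("velogcn")),
            r_version = R.version.string,
            seed = seed,
            config = lapply(config[c("preprocess", "model", "objective",
                                     "gene_filter")], unclass),
            numeric_fingerprint = sprintf("%.17g", sum(velocity(x)^2)))
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        list(dataset = x, model = fit$model, log = fit$log,
             summary = summary, outdir = outdir, velocity_graph = vg,
             arrows = arrows, drivers = drivers)
    }, error = function(e) {
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE)
    })
    invisible(res)
}
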