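# End-to-end orchestration: simulate/load -> QC filter -> windows -> sweep
# scan -> SFS -> demographic fit, with a manifest and resolved-config copy
# for reproducibility.

#' Assemble a pipeline configuration
#'
#' Either a path to a YAML file or arguments; \code{seed} is mandatory.
#' Fields: \code{vcf}, \code{popmap}, \code{genes} (input paths; ignored
#' when \code{simulate} is given), \code{simulate} (list of
#' \code{\link{simulationConfig}} arguments), \code{stages} (character
#' subset of filter/windows/sweep/sfs/fit), \code{windowSize},
#' \code{windowStep}, \code{minScaffold}, \code{q}, \code{projections},
#' \code{scenario}, \code{outDir}.
#'
#' @param path optional YAML file.
#' @param ... fields overriding the file.
#' @return config list (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(path = NULL, ...) {
    cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
    dots <- list(...)
    cfg[names(dots)] <- dots
    defaults <- list(stages = c("filter", "windows", "sweep", "sfs", "fit"),
                     windowSize = 10000L, windowStep = 5000L,
                     minScaffold = 10000L, q = 0.05, projections = NULL,
                     scenario = "model2", outDir = tempfile("run"))
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    if (is.null(cfg$seed)) stop("seed is mandatory")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order (filter, windows, sweep, sfs, fit)
#' on simulated or file inputs; every stage's outputs land under a
#' run-stamped directory together with a resolved copy of the
#' configuration and a manifest (input hashes, seed, package version).
#' A failing stage halts with a stage-named error; earlier outputs remain.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with the per-stage results and \code{dir}, the run
#'   directory.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    res <- list(dir = config$outDir)
    manifest <- list(seed = config$seed,
                     package = as.character(utils::packageVersion("SweepDemes")),
                     stages = config$stages)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    cfg_out <- config
    class(cfg_out) <- NULL
    cfg_out$simulate <- NULL
    yaml::write_yaml(cfg_out, file.path(config$outDir, "config.yaml"))
    if (!is.null(config$simulate)) {
        sim <- stage("simulate", {
            sc <- do.call(simulationConfig,
                          c(config$simulate, list(seed = config$seed)))
            simulateCohort(sc)
        })
        cohort <- sim$cohort
        genes <- sim$genes
        res$truth <- sim$truth
        writeSimulation(sim, file.path(config$outDir, "sim"))
    } else {
        cohort <- stage("load", {
            co <- readVcfCohort(config$vcf)
            attachPopulations(co, readPopmap(config$popmap))
        })
        genes <- if (!is.null(config$genes))
            stage("load", readGeneTrack(config$genes)) else NULL
        manifest$inputs <- as.list(tools::md5sum(
            stats::na.omit(c(config$vcf, config$popmap, config$genes))))
    }
    if ("filter" %in% config$stages) {
        f <- stage("filter", filterVariants(cohort))
        cohort <- f$cohort
        write.table(f$report, file.path(config$outDir, "filter_report.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$filterReport <- f$report
    }
    wild <- sampleIndices(cohort, group = "wild", scheme = "production")
    dom <- setdiff(seq_len(ncol(cohort)), wild)
    windows <- NULL
    if ("windows" %in% config$stages) {
        ws <- stage("windows", {
            windows <- makeWindows(scaffoldLengths(cohort),
                                   config$windowSize, config$windowStep,
                                   config$minScaffold)
            windowDiversityStats(cohort, wild, dom, windows)
        })
        df <- data.frame(scaffold = as.character(seqnames(ws)),
                         start = start(ws) - 1L, end = end(ws),
                         as.data.frame(S4Vectors::mcols(ws)))
        write.table(df, file.path(config$outDir, "windows.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$windowStats <- ws
    }
    if ("sweep" %in% config$stages) {
        sw <- stage("sweep", {
            out <- jointOutliers(res$windowStats, q = config$q)
            regions <- mergeRegions(res$windowStats, out$selected)
            ann <- if (!is.null(genes)) annotateGenes(regions, genes)
            list(outliers = out, regions = regions, genes = ann)
        })
        bed <- data.frame(scaffold = as.character(seqnames(sw$regions)),
                          start = start(sw$regions) - 1L,
                          end = end(sw$regions))
        write.table(bed, file.path(config$outDir, "sweep_regions.bed"),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        if (!is.null(sw$genes))
            writeLines(sw$genes$genes,
                       file.path(config$outDir, "sweep_genes.txt"))
        res$sweep <- sw
    }
    if ("sfs" %in% config$stages) {
        sfs <- stage("sfs", {
            pops <- list(
                wild = wild,
                meat = sampleIndices(cohort, group = "meat",
                                     scheme = "production"),
                eggdp = sampleIndices(cohort, group = c("egg",
                                                        "dual-purpose"),
                                      scheme = "production"))
            proj <- config$projections
            if (is.null(proj))
                proj <- chooseProjection(cohort, pops)$projections
            jointFoldedSfs(cohort, pops, proj)
        })
        writeFoldedSfs(sfs, file.path(config$outDir, "spectrum.sfs"))
        res$sfs <- sfs
    }
    if ("fit" %in% config$stages) {
        fit <- stage("fit", {
            start <- duckDomesticationModel()$model
            free <- c("TDOM", "nuD0")
            fitModel(start, res$sfs, free,
                     lower = c(TDOM = 1e-4, nuD0 = 1e-4),
                     upper = c(TDOM = 0.2, nuD0 = 0.2),
                     nReps = 2000L, seed = config$seed, restarts = 3L,
                     maxit = 100L)
        })
        est <- toRealUnits(fit@model@params[fit@free],
                           Nref = if (!is.null(res$truth))
                               res$truth$Nref else 1e5)
        write.table(est, file.path(config$outDir, "fit.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        res$fit <- fit
    }
    manifest$outputs <- list.files(config$outDir)
    jsonlite::write_json(manifest, file.path(config$outDir,
                                             "manifest.json"),
                         auto_unbox = TRUE)
    res
}
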