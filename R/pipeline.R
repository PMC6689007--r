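#' Assemble and validate a pipeline configuration
#'
#' Defaults mirror the method's published parameterization: QC keeps cells
#' with >= 1000 detected genes and a mitochondrial fraction < 0.05;
#' library-size normalization with pseudocount 1.1; HVG selection at mean > 1
#' and sd > 1; t-SNE with 30 initial dimensions, perplexity 30, 1000
#' iterations; DBSCAN with eps = 5, minPts = 15; cell-states need >= 5 cells;
#' diffusion maps with k = 30 and 10 components; mixture selection up to
#' kMax = 6. Every default is overridable and recorded in the run report.
#'
#' @param counts a \code{SingleCellExperiment} of raw counts, a count matrix,
#'   or a path readable by [readCounts()]; NULL when `expression` is given.
#' @param expression a pre-normalized genes x cells matrix/container or a
#'   TSV/CSV path (skips QC/normalization).
#' @param network a [GeneNetwork-class] or an edge-list path.
#' @param normalization "library" (counts, pseudocount 1.1) or "fpkm"
#'   (log2(x + 1)).
#' @param minGenes,maxMito,hvgMean,hvgSd,kMax,initialDims,perplexity,maxIter
#'   stage parameters (see above).
#' @param eps,minPts,minCells,k,nDCs stage parameters (see above).
#' @param seeds named list of per-stage seeds (embed, potency).
#' @param outDir optional output directory for stage artifacts (TSVs).
#' @param mito mitochondrial gene rule for [readCounts()] (prefix or file).
#' @return a validated config (list, class "scPotencyConfig").
#' @export
runConfig <- function(counts = NULL, expression = NULL, network = NULL,
                      normalization = c("library", "fpkm"),
                      minGenes = 1000L, maxMito = 0.05,
                      hvgMean = 1, hvgSd = 1, kMax = 6L,
                      initialDims = 30L, perplexity = 30, maxIter = 1000L,
                      eps = 5, minPts = 15L, minCells = 5L,
                      k = 30L, nDCs = 10L,
                      seeds = list(embed = 42L, potency = 42L),
                      outDir = NULL, mito = "MT-") {
    cfg <- list(counts = counts, expression = expression, network = network,
                normalization = match.arg(normalization),
                minGenes = minGenes, maxMito = maxMito,
                hvgMean = hvgMean, hvgSd = hvgSd, kMax = kMax,
                initialDims = initialDims, perplexity = perplexity,
                maxIter = maxIter, eps = eps, minPts = minPts,
                minCells = minCells, k = k, nDCs = nDCs,
                seeds = utils::modifyList(list(embed = 42L, potency = 42L),
                                          as.list(seeds)),
                outDir = outDir, mito = mito)
    class(cfg) <- "scPotencyConfig"
    validateConfig(cfg)
    cfg
}

validateConfig <- function(cfg) {
    fail <- function(...) stop("config error: ", ..., call. = FALSE)
    if (is.null(cfg$counts) && is.null(cfg$expression))
        fail("one of `counts` or `expression` is required")
    if (is.null(cfg$network))
        fail("a `network` (GeneNetwork or edge-list path) is required for ",
             "the entropy stage")
    if (is.character(cfg$network) && !file.exists(cfg$network))
        fail("network path does not exist: ", cfg$network)
    if (cfg$minGenes < 0) fail("minGenes must be nonnegative")
    if (cfg$maxMito < 0 || cfg$maxMito > 1) fail("maxMito must lie in [0, 1]")
    if (cfg$kMax < 1) fail("kMax must be at least 1")
    if (cfg$k < 2) fail("k must be at least 2")
    invisible(TRUE)
}

stageRecord <- function(report, name, params, shapes, elapsed,
                        warnings = character()) {
    report$stages[[name]] <- list(name = name, params = params,
                                  shapes = shapes,
                                  elapsed_sec = round(elapsed, 3),
                                  warnings = warnings, status = "ok")
    report
}

writeTSV <- function(df, outDir, name) {
    if (!is.null(outDir))
        utils::write.table(df, file.path(outDir, paste0(name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full potency-landscape pipeline
#'
#' Stages, in order: QC filter -> normalization -> signaling entropy (SR) ->
#' potency-state inference -> landscape (embedding, clustering, cell-states,
#' densities) -> trajectory (root, diffusion map, DPT, tips). Identical
#' config and seeds give identical outputs. On a stage failure the completed
#' stages' artifacts are kept, the report marks the failed stage, and the
#' error is re-signalled.
#'
#' @param config from [runConfig()].
#' @return a run report (list, class "scPotencyReport"): per-stage parameters
#'   and shapes, plus headline numbers (cells kept, K, state sizes, root id,
#'   tip ids) and the results themselves in `$results`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "scPotencyConfig"))
    validateConfig(config)
    if (!is.null(config$outDir))
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    report <- list(stages = list(), headline = list(), results = list(),
                   config = config[!(names(config) %in%
                                     c("counts", "expression", "network"))])
    class(report) <- "scPotencyReport"
    failed <- NULL
    runStage <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        ws <- character()
        res <- withCallingHandlers(
            tryCatch(fun(), error = function(e) e),
            warning = function(w) {
                ws <<- c(ws, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        if (inherits(res, "error")) {
            report$stages[[name]] <<- list(name = name, status = "failed",
                                           error = conditionMessage(res))
            failed <<- res
            return(NULL)
        }
        report <<- stageRecord(report, name, res$params, res$shapes,
                               proc.time()[["elapsed"]] - t0, ws)
        res$value
    }
    finish <- function() {
        if (!is.null(config$outDir))
            exportReport(report,
                         file.path(config$outDir, "report.json"), "json")
        if (!is.null(failed)) stop("pipeline stage failed: ",
                                   conditionMessage(failed), call. = FALSE)
        report
    }

    net <- if (is.character(config$network)) readEdgeList(config$network)
           else config$network

    expr <- NULL
    if (!is.null(config$expression)) {
        expr <- if (is.character(config$expression))
            as.matrix(utils::read.table(config$expression, header = TRUE,
                                        sep = "\t", row.names = 1L,
                                        check.names = FALSE))
        else getExprMatrix(config$expression)
        report$stages[["qc"]] <- list(name = "qc", status = "skipped",
                                      reason = "pre-normalized input")
        report$stages[["normalize"]] <- list(name = "normalize",
                                             status = "skipped",
                                             reason = "pre-normalized input")
    } else {
        cm <- if (is.character(config$counts))
            readCounts(config$counts, mito = config$mito) else config$counts
        qcRes <- runStage("qc", function() {
            out <- qcFilter(cm, config$minGenes, config$maxMito)
            writeTSV(out$report, config$outDir, "qc_report")
            list(value = out,
                 params = list(minGenes = config$minGenes,
                               maxMito = config$maxMito),
                 shapes = list(cells_in = ncol(cm),
                               cells_kept = sum(out$report$kept)))
        })
        if (is.null(qcRes)) return(finish())
        report$headline$cells_kept <- sum(qcRes$report$kept)
        normRes <- runStage("normalize", function() {
            sce <- if (config$normalization == "library")
                normalizeLibrary(qcRes$counts)
            else normalizeFPKM(SummarizedExperiment::assay(qcRes$counts,
                                                           "counts"))
            list(value = sce,
                 params = list(normalization = config$normalization),
                 shapes = list(genes = nrow(sce), cells = ncol(sce)))
        })
        if (is.null(normRes)) return(finish())
        expr <- getExprMatrix(normRes)
    }

    srp <- runStage("sr", function() {
        p <- srProfile(expr, net)
        writeTSV(as.data.frame(p), config$outDir, "sr_profile")
        list(value = p, params = list(),
             shapes = list(network_genes = numNodes(net), cells = ncol(expr)))
    })
    if (is.null(srp)) return(finish())

    pot <- runStage("potency", function() {
        y <- logitSR(srp)
        if (any(!is.finite(y)))
            stop("logit-SR is infinite for ", sum(!is.finite(y)), " cell(s)")
        m <- inferPotencyStates(y, kMax = config$kMax,
                                seed = config$seeds$potency)
        writeTSV(data.frame(cell_id = cellIds(srp), logitSR = y,
                            state = stateLabels(m)),
                 config$outDir, "potency_states")
        list(value = m,
             params = list(kMax = config$kMax, seed = config$seeds$potency),
             shapes = list(K = numStates(m),
                           state_sizes = as.integer(table(stateLabels(m)))))
    })
    if (is.null(pot)) return(finish())
    report$headline$K <- numStates(pot)
    report$headline$state_sizes <- as.integer(table(stateLabels(pot)))

    hvg <- selectHVG(expr, config$hvgMean, config$hvgSd)
    exprHVG <- if (length(hvg) >= 2) expr[hvg, , drop = FALSE] else expr

    land <- runStage("landscape", function() {
        l <- computeLandscape(exprHVG, stateLabels(pot),
                              eps = config$eps, minPts = config$minPts,
                              minCells = config$minCells,
                              initialDims = config$initialDims,
                              perplexity = config$perplexity,
                              maxIter = config$maxIter,
                              seed = config$seeds$embed)
        writeTSV(data.frame(cell_id = cellIds(srp), l@coords,
                            cluster = l@clusterLabels),
                 config$outDir, "embedding")
        writeTSV(l@cellStateTable, config$outDir, "cell_states")
        list(value = l,
             params = list(hvg = length(hvg), eps = config$eps,
                           minPts = config$minPts,
                           minCells = config$minCells,
                           seed = config$seeds$embed),
             shapes = list(clusters = max(l@clusterLabels),
                           peripheral = sum(l@clusterLabels == 0L)))
    })
    if (is.null(land)) return(finish())
    report$headline$n_clusters <- max(land@clusterLabels)

    traj <- runStage("trajectory", function() {
        root <- selectRoot(srp)
        dm <- diffusionMap(t(exprHVG), k = min(config$k, ncol(exprHVG) - 1L),
                           nDCs = config$nDCs)
        dm <- diffusionPseudotime(dm, root)
        tips <- findTips(pseudotime(dm), land@clusterLabels)
        writeTSV(data.frame(cell_id = cellIds(srp), dpt = pseudotime(dm),
                            dm@components),
                 config$outDir, "trajectory")
        list(value = list(dmap = dm, root = root, tips = tips),
             params = list(k = config$k, nDCs = config$nDCs),
             shapes = list(components = length(dm@eigenvalues)))
    })
    if (is.null(traj)) return(finish())
    report$headline$root_cell <- cellIds(srp)[traj$root]
    report$headline$tip_cells <- cellIds(srp)[c(traj$tips$global,
                                                traj$tips$perCluster)]

    report$results <- list(sr = srp, potency = pot, landscape = land,
                           trajectory = traj, hvg = hvg)
    finish()
}

# strip non-reproducible / non-serializable parts of a report
reportBody <- function(report, timings = FALSE) {
    stages <- lapply(report$stages, function(s) {
        if (!timings) s$elapsed_sec <- NULL
        s
    })
    cfg <- report$config
    cfg$outDir <- NULL   # a path, not part of the analysis
    list(stages = stages, headline = report$headline, config = cfg)
}

#' Export a run report
#'
#' JSON (lossless round-trip via [readReport()]) or TSV (one row per stage).
#' Timings are excluded by default so identical runs serialize identically.
#'
#' @param report from [runPipeline()].
#' @param path output file.
#' @param format "json" or "tsv".
#' @param timings include per-stage wall-clock seconds.
#' @return `path`, invisibly.
#' @export
exportReport <- function(report, path, format = c("json", "tsv"),
                         timings = FALSE) {
    format <- match.arg(format)
    body <- reportBody(report, timings = timings)
    if (format == "json") {
        jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    } else {
        rows <- do.call(rbind, lapply(body$stages, function(s)
            data.frame(stage = s$name, status = s$status,
                       params = jsonlite::toJSON(s$params, auto_unbox = TRUE),
                       shapes = jsonlite::toJSON(s$shapes, auto_unbox = TRUE),
                       stringsAsFactors = FALSE)))
        utils::write.table(rows, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read back a JSON run report
#' @param path JSON file written by [exportReport()].
#' @return the report body (list).
#' @export
readReport <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
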