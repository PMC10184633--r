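#' Read a pipeline configuration file
#'
#' YAML configuration driving [runPipeline()]. Top-level keys: `seed`,
#' `thresholds` (named [ThresholdConfig-class] overrides), either `simulate`
#' (keys `layers`, `n_per_class`, `times_h`, `n_replicates`, `noise_sd`) or
#' `inputs` (list of `layer`/`scale`/`path` entries), `impute`
#' (`downshift` or `none`), `classify` (`baseline`, `rule`) and an optional
#' `network` block (`edges`, `hubs`, `keywords`, `registry`, `min_score`).
#' Relative paths are resolved against the config file's directory.
#'
#' @param path YAML file path.
#' @return config list with attribute `dir` (the config directory).
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    attr(cfg, "dir") <- dirname(normalizePath(path))
    cfg
}

.resolvePath <- function(p, dir) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(dir, p)
}

.stageWrite <- function(df, path) {
    tmp <- paste0(path, ".partial")
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    invisible(path)
}

.configHash <- function(cfg) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                null = "null"), tmp)
    unname(tools::md5sum(tmp))
}

.runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Chains simulate (or load) -> impute -> differential -> classify ->
#' events -> network, writing one TSV per stage plus a JSON run manifest
#' (config hash, seed, per-stage row counts). Re-running with an identical
#' config and seed reproduces every output byte-identically. A stage error
#' aborts with a stage-labeled message; files of the failing stage keep a
#' `.partial` suffix.
#'
#' @param config config list from [readPipelineConfig()], or a YAML path.
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, a list with the stage tables and the manifest.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir <- attr(config, "dir"); if (is.null(dir)) dir <- "."
    if (!is.null(seed)) config$seed <- as.integer(seed)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    thr <- do.call(thresholdConfig, as.list(config$thresholds))
    counts <- list()

    ## --- data stage: simulate or load ------------------------------------
    data <- .runStage("data", {
        if (!is.null(config$simulate)) {
            sim <- config$simulate
            layers <- unlist(sim$layers)
            nPer <- unlist(sim$n_per_class)
            plans <- lapply(seq_along(layers), function(i)
                makeTruthPlan(nPer, layer = layers[i], seed = seed + i))
            plan <- do.call(rbind, plans)
            scfg <- simConfig(
                nFeaturesPerClass = nPer,
                timesH = if (is.null(sim$times_h))
                    c(0, 0.0333, 0.5, 4, 8, 12, 24) else unlist(sim$times_h),
                nReplicates = if (is.null(sim$n_replicates)) 3L
                              else sim$n_replicates,
                noiseSd = if (is.null(sim$noise_sd)) 0.2 else sim$noise_sd,
                seed = seed)
            ds <- generateDataset(scfg, plan)
            dataDir <- file.path(outDir, "data")
            writeFixture(ds, dataDir, overwrite = TRUE)
            ds
        } else if (!is.null(config$inputs)) {
            mats <- list()
            for (inp in config$inputs) {
                p <- .resolvePath(inp$path, dir)
                if (!file.exists(p)) stop("missing input path: ", p)
                mats[[inp$layer]] <- readOmicsMatrix(p, inp$layer, inp$scale)
            }
            list(matrices = mats, truth = NULL)
        } else stop("config needs a 'simulate' or 'inputs' block")
    })
    counts$features <- sum(vapply(data$matrices, nrow, 0L))

    ## --- impute stage -----------------------------------------------------
    mats <- .runStage("impute", {
        mode <- if (is.null(config$impute)) "downshift" else config$impute
        lapply(seq_along(data$matrices), function(i) {
            m <- data$matrices[[i]]
            if (mode == "downshift" && omicsLayer(m) %in% .PROTEOMIC_LAYERS &&
                anyNA(omicsValues(m)))
                imputeDownshiftedNormal(m, thr@imputeWidth, thr@imputeShift,
                                        seed = seed + 100L + i)
            else m
        })
    })
    names(mats) <- names(data$matrices)

    ## --- differential stage -----------------------------------------------
    diffAll <- .runStage("differential", {
        tabs <- lapply(mats, runDifferential, cfg = thr)
        out <- do.call(rbind, tabs)
        rownames(out) <- NULL
        .stageWrite(out, file.path(outDir, "differential.tsv"))
        out
    })
    counts$differential_rows <- nrow(diffAll)
    counts$significant_events <- sum(diffAll$significant)

    ## --- classify stage ---------------------------------------------------
    classes <- .runStage("classify", {
        cl <- config$classify
        baseline <- if (is.null(cl$baseline)) "ctrl_course" else cl$baseline
        rule <- if (is.null(cl$rule)) "s4-or-e3" else cl$rule
        tabs <- lapply(names(mats), function(ly)
            classifyResponses(mats[[ly]],
                              diffAll[diffAll$layer == ly, , drop = FALSE],
                              thr, baseline = baseline, rule = rule))
        out <- do.call(rbind, tabs)
        .stageWrite(out, file.path(outDir, "classes.tsv"))
        out
    })
    counts$classified_features <- nrow(classes)

    ## --- events stage -----------------------------------------------------
    events <- .runStage("events", {
        curves <- do.call(rbind, lapply(names(mats), function(ly)
            do.call(rbind, lapply(c("TNF", "IFN", "TNF_IFN"), function(cond)
                cumulativeEventCurve(diffAll, ly, cond)))))
        .stageWrite(curves, file.path(outDir, "event_curves.tsv"))
        comb <- diffAll[diffAll$condition == "TNF_IFN", , drop = FALSE]
        ordering <- withCallingHandlers(onsetOrdering(comb),
                                        warning = function(w)
                                            invokeRestart("muffleWarning"))
        .stageWrite(ordering, file.path(outDir, "onset_ordering.tsv"))
        list(curves = curves, ordering = ordering)
    })
    counts$event_curve_rows <- nrow(events$curves)

    ## --- network stage (optional) ------------------------------------------
    network <- NULL
    if (!is.null(config$network)) {
        network <- .runStage("network", {
            nw <- config$network
            edges <- readEdgeTable(.resolvePath(nw$edges, dir))
            minScore <- if (is.null(nw$min_score)) thr@edgeScoreMin
                        else nw$min_score
            kept <- filterEdges(edges, minScore)
            .stageWrite(kept, file.path(outDir, "filtered_edges.tsv"))
            geneClasses <- collapseFeaturesToGenes(classes)
            .stageWrite(geneClasses, file.path(outDir, "gene_classes.tsv"))
            out <- list(edges = kept, geneClasses = geneClasses)
            if (!is.null(nw$hubs)) {
                hubs <- read.delim(.resolvePath(nw$hubs, dir),
                                   stringsAsFactors = FALSE)
                comp <- hubComposition(geneClasses, hubs)
                .stageWrite(comp, file.path(outDir, "hub_composition.tsv"))
                out$hubComposition <- comp
            }
            if (!is.null(nw$keywords)) {
                kw <- readKeywordTable(.resolvePath(nw$keywords, dir))
                rl <- classifyReceptorsLigands(kw, edges, thr)
                .stageWrite(rl, file.path(outDir, "receptor_ligand.tsv"))
                out$receptorLigand <- rl
            }
            if (!is.null(nw$registry) && "secretome" %in% names(mats)) {
                reg <- readGeneRegistry(.resolvePath(nw$registry, dir))
                ov <- withCallingHandlers(
                    cytokineOverlay(diffAll[diffAll$layer == "secretome", ,
                                            drop = FALSE], reg),
                    warning = function(w) invokeRestart("muffleWarning"))
                .stageWrite(ov, file.path(outDir, "cytokine_overlay.tsv"))
                out$cytokineOverlay <- ov
            }
            out
        })
        counts$network_edges <- nrow(network$edges)
    }

    ## --- manifest ----------------------------------------------------------
    manifest <- list(pipeline = "inflamap",
                     version = as.character(utils::packageVersion("inflamap")),
                     seed = seed, config_hash = .configHash(config),
                     counts = counts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(matrices = mats, differential = diffAll,
                   classes = classes, events = events, network = network,
                   manifest = manifest))
}
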