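## End-to-end orchestration: merge -> Step 1 -> Step 2 -> Step 3 ->
## confidence, plus the file-level runner with config and run manifest.

#' Merge a synthetic pool into a CellAssignmentTable
#'
#' Convenience wrapper: merges the tool outputs of a [simulatePool()] result
#' exactly as [mergeToolOutputs()] would merge parsed files.
#'
#' @param pool a `SyntheticPool`.
#' @param ... passed to [mergeToolOutputs()].
#' @return a [CellAssignmentTable].
#' @export
poolAssignmentTable <- function(pool, ...) {
    stopifnot(inherits(pool, "SyntheticPool"))
    mergeToolOutputs(pool$toolOutputs, ...)
}

#' Run the full ensemble on a merged table
#'
#' The core pipeline over an in-memory [CellAssignmentTable]:
#' accuracy-weighted probabilistic ensemble (Step 1), graph-based doublet
#' detection with the kurtosis parameter sweep (Step 2, unless disabled),
#' ensemble-independent doublet rescue from the nominated tools (Step 3,
#' unless disabled), then per-tool probability calibration and the singlet
#' confidence score with the retention threshold.
#'
#' @param table a [CellAssignmentTable].
#' @param exDR expected doublet rate; required when Step 2 is enabled.
#' @param step2,step3 logical switches for the doublet-detection steps.
#' @param nominees Step-3 tool nominations (default Demuxalot and Vireo).
#' @param nCDGrid,pTGrid parameter-sweep grids (defaults as in
#'   [parameterSweep()]).
#' @param confidenceThreshold singlet retention threshold (default 1.00).
#' @param weights optional [ToolWeights] or named numeric vector overriding
#'   the consensus-proxy weight estimation.
#' @param reference optional ground-truth labels used for weighting and
#'   calibration instead of the consensus proxy (validation runs only).
#' @return an [EnsembleResult].
#' @export
demultiplexPool <- function(table, exDR = NULL, step2 = TRUE, step3 = TRUE,
                            nominees = c("demuxalot", "vireo"),
                            nCDGrid = seq(50L, 300L, 50L), pTGrid = NULL,
                            confidenceThreshold = 1.00, weights = NULL,
                            reference = NULL) {
    stopifnot(is(table, "CellAssignmentTable"))
    ids <- toolIds(table)
    if (is.null(weights)) {
        weights <- estimateToolWeights(table, reference = reference)
    } else if (!is(weights, "ToolWeights")) {
        weights <- new("ToolWeights", weights = weights[ids],
                       referenceKind = "ground_truth",
                       nReference = stats::setNames(integer(length(ids)), ids))
    }
    probs <- lapply(ids, function(id) perToolClassProbs(table, id))
    names(probs) <- ids
    ensemble <- weightedEnsemble(probs, weights)
    step1 <- assignStep1(ensemble)
    labels <- stats::setNames(step1$label, step1$barcode)
    step1Prob <- stats::setNames(step1$prob, step1$barcode)
    sweep <- NULL
    step2Flag <- stats::setNames(rep(FALSE, length(labels)), names(labels))
    if (step2) {
        if (is.null(exDR))
            stop("exDR must be set when Step 2 is enabled")
        features <- doubletFeatureMatrix(table)
        sweep <- parameterSweep(features, exDR, nCDGrid = nCDGrid,
                                pTGrid = pTGrid)
        g2 <- applyGraphDoublets(labels, sweep)
        step2Flag[names(labels)] <- g2$labels != labels
        labels <- g2$labels
    }
    step3Flag <- stats::setNames(rep(FALSE, length(labels)), names(labels))
    if (step3) {
        g3 <- applyIndependentDoublets(labels, table, nominees = nominees)
        step3Flag[names(labels)] <- g3$labels != labels
        labels <- g3$labels
    }
    calibration <- calibrateTools(table, reference = reference)
    conf <- confidenceScores(labels, step1Prob, calibration, table,
                             threshold = confidenceThreshold)
    bcs <- barcodes(table)
    tab <- S4Vectors::DataFrame(barcode = bcs)
    for (id in ids) {
        t <- getTool(table, id)
        tab[[paste0(id, "_label")]] <- unname(cellLabels(t))
        tab[[paste0(id, "_prob")]] <- t@prob
    }
    tab$step1_label <- unname(stats::setNames(step1$label, step1$barcode)[bcs])
    tab$step1_prob <- unname(step1Prob[bcs])
    tab$step2_doublet <- unname(step2Flag[bcs])
    tab$step3_doublet <- unname(step3Flag[bcs])
    tab$final_label <- unname(labels[bcs])
    tab$confidence <- conf$confidence[match(bcs, conf$barcode)]
    tab$status <- conf$status[match(bcs, conf$barcode)]
    new("EnsembleResult", table = tab, weights = weights,
        calibration = calibration, sweep = sweep,
        params = list(toolIds = ids, exDR = exDR, step2 = step2,
                      step3 = step3, nominees = nominees,
                      confidenceThreshold = confidenceThreshold))
}

.read_tool_input <- function(id, path) {
    switch(id,
           demuxlet = readDemuxletBest(path, "demuxlet"),
           freemuxlet = readDemuxletBest(path, "freemuxlet"),
           souporcell = readSouporcellClusters(path),
           vireo = readVireoDonorIds(path),
           demuxalot = readDemuxalotProbs(path),
           stop(sprintf("unknown tool id in config: '%s'", id)))
}

#' Run the pipeline from a config
#'
#' File-level entry point: reads each configured tool output with its native
#' parser, merges them, runs [demultiplexPool()], and writes the ensemble
#' output TSV, a sweep diagnostic TSV and a JSON run manifest (config echo,
#' tool weights, calibration, sweep choice, package version and seed) into
#' the output directory.
#'
#' The config is a nested list (or path to a YAML file) with blocks:
#' `inputs` (named tool-id -> file path), `output_dir`, optional `mode`
#' (`genotype_aware`/`genotype_free`, bookkeeping only), `merge`
#' (`barcode_policy`, `strip_suffix`, `donor_map`), `step1`
#' (`weights_override`), `step2` (`exDR`, `nCD_grid`, `pT_grid`, `disable`),
#' `step3` (`nominees`, `disable`) and `confidence` (`threshold`,
#' `tool_thresholds`).
#'
#' @param config nested list or YAML file path.
#' @return the [EnsembleResult], invisibly.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    known <- c("inputs", "output_dir", "mode", "merge", "step1", "step2",
               "step3", "confidence", "seed")
    bad <- setdiff(names(config), known)
    if (length(bad))
        stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    if (is.null(config$inputs) || length(config$inputs) < 2L)
        stop("config must list >=2 tool input files under 'inputs'")
    for (p in unlist(config$inputs))
        if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
    outDir <- config$output_dir
    if (is.null(outDir)) stop("config must set 'output_dir'")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    outputs <- lapply(names(config$inputs), function(id)
        .read_tool_input(id, config$inputs[[id]]))
    mg <- config$merge
    table <- mergeToolOutputs(
        outputs,
        barcodePolicy = if (is.null(mg$barcode_policy)) "intersection" else mg$barcode_policy,
        stripSuffix = isTRUE(mg$strip_suffix),
        donorMap = mg$donor_map,
        toolThresholds = unlist(config$confidence$tool_thresholds))
    step2On <- !isTRUE(config$step2$disable)
    if (step2On && is.null(config$step2$exDR))
        stop("step2.exDR must be set when Step 2 is enabled")
    result <- demultiplexPool(
        table,
        exDR = config$step2$exDR,
        step2 = step2On,
        step3 = !isTRUE(config$step3$disable),
        nominees = if (is.null(config$step3$nominees))
            c("demuxalot", "vireo") else unlist(config$step3$nominees),
        nCDGrid = if (is.null(config$step2$nCD_grid))
            seq(50L, 300L, 50L) else unlist(config$step2$nCD_grid),
        pTGrid = config$step2$pT_grid,
        confidenceThreshold = if (is.null(config$confidence$threshold))
            1.00 else config$confidence$threshold,
        weights = unlist(config$step1$weights_override))
    writeEnsembleOutput(result, file.path(outDir, "ensemble_output.tsv"))
    if (!is.null(result@sweep))
        utils::write.table(result@sweep@grid,
                           file.path(outDir, "sweep_diagnostics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
        package = "demuxEnsemble",
        version = as.character(utils::packageVersion("demuxEnsemble")),
        config = config,
        tool_weights = as.list(result@weights@weights),
        calibration = result@calibration,
        sweep = if (is.null(result@sweep)) NULL else
            list(nCD = result@sweep@chosenNCD, pT = result@sweep@chosenPT,
                 path = result@sweep@selectionPath)
    )
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(result)
}
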