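## Merging tool outputs over a shared barcode universe, and reading/writing
## the final ensemble output table.

.GENOTYPE_AWARE <- c("demuxalot", "demuxlet", "freemuxlet", "vireo")

.DEFAULT_THRESHOLDS <- c(demuxalot = 0.9, demuxlet = 0.9, freemuxlet = 0.9,
                         souporcell = 0.8, vireo = 0.9)

## Reindex a ToolOutput onto a barcode universe; absent barcodes become
## unassigned with missing probability and features.
.align_tool <- function(t, universe) {
    idx <- match(universe, t@barcode)
    feats <- t@features[idx, , drop = FALSE]
    rownames(feats) <- NULL
    cp <- t@classProbs
    if (!is.null(cp)) {
        cp <- cp[idx, , drop = FALSE]
        rownames(cp) <- universe
    }
    call <- t@call[idx]
    call[is.na(idx)] <- .UNS
    new("ToolOutput", toolId = t@toolId, barcode = universe, call = call,
        donor = t@donor[idx], prob = t@prob[idx], features = feats,
        classProbs = cp)
}

.tool_donors <- function(t) sort(unique(t@donor[!is.na(t@donor)]))

#' Merge constituent tool outputs into a CellAssignmentTable
#'
#' Aligns two or more [ToolOutput] objects onto a common, lexicographically
#' ordered barcode universe (the intersection of the tools' barcodes by
#' default, or their union) and assembles the merged per-cell table the
#' ensemble operates on. Under the union policy a tool missing a barcode
#' contributes an unassigned call with missing probability and features. The
#' donor roster is the union of donor ids seen by any tool (plus any donors
#' introduced by `donorMap`). Merging is invariant to the order of `outputs`:
#' tools are stored sorted by tool id.
#'
#' Genotype-free tools (Souporcell) label cells with cluster ids rather than
#' donor ids; an optional `donorMap` (cluster id -> donor id) reconciles the
#' namespaces. Without it, namespaces are kept verbatim. Fully disjoint donor
#' namespaces between two genotype-aware tools raise an error advising a
#' donor-name mapping.
#'
#' @param outputs list of [ToolOutput] objects with distinct tool ids.
#' @param barcodePolicy `"intersection"` (default) or `"union"`.
#' @param stripSuffix if `TRUE`, a trailing `-<digit>` CellRanger suffix is
#'   stripped from all barcodes before matching.
#' @param donorMap optional named character vector (or path to a two-column
#'   TSV `cluster_id<TAB>donor_id`) mapping cluster ids to donor ids.
#' @param toolThresholds named numeric vector of per-tool probability
#'   thresholds; defaults are 0.9 for the genotype-aware tools and 0.8 for
#'   Souporcell.
#' @return a [CellAssignmentTable].
#' @export
mergeToolOutputs <- function(outputs,
                             barcodePolicy = c("intersection", "union"),
                             stripSuffix = FALSE, donorMap = NULL,
                             toolThresholds = NULL) {
    barcodePolicy <- match.arg(barcodePolicy)
    if (length(outputs) < 2L)
        stop("need at least two tool outputs to merge")
    ids <- vapply(outputs, toolId, character(1))
    if (anyDuplicated(ids))
        stop("tool ids must be distinct")
    if (is.character(donorMap) && length(donorMap) == 1L && file.exists(donorMap)) {
        mp <- utils::read.table(donorMap, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE, colClasses = "character")
        donorMap <- stats::setNames(mp[[2L]], mp[[1L]])
    }
    if (stripSuffix)
        outputs <- lapply(outputs, function(t) {
            t@barcode <- sub("-[0-9]$", "", t@barcode)
            if (anyDuplicated(t@barcode))
                stop(sprintf("tool '%s': stripping the barcode suffix created duplicates",
                             t@toolId))
            t
        })
    if (!is.null(donorMap))
        outputs <- lapply(outputs, function(t) {
            hit <- !is.na(t@donor) & t@donor %in% names(donorMap)
            t@donor[hit] <- unname(donorMap[t@donor[hit]])
            if (!is.null(t@classProbs)) {
                cn <- colnames(t@classProbs)
                ren <- cn %in% names(donorMap)
                colnames(t@classProbs)[ren] <- unname(donorMap[cn[ren]])
            }
            t
        })
    ## disjoint donor namespaces across genotype-aware tools are a user error
    ga <- outputs[ids %in% .GENOTYPE_AWARE]
    if (length(ga) >= 2L) {
        sets <- lapply(ga, .tool_donors)
        nonEmpty <- which(lengths(sets) > 0L)
        for (i in nonEmpty) for (j in nonEmpty) {
            if (i < j && !length(intersect(sets[[i]], sets[[j]])))
                stop(sprintf(paste0("donor namespaces of '%s' and '%s' are fully ",
                                    "disjoint; supply a donor-name mapping file"),
                             ga[[i]]@toolId, ga[[j]]@toolId))
        }
    }
    bcs <- lapply(outputs, barcodes)
    universe <- if (barcodePolicy == "intersection")
        Reduce(intersect, bcs) else Reduce(union, bcs)
    if (!length(universe))
        stop("empty barcode universe after merging")
    universe <- sort(universe, method = "radix")
    ord <- order(ids, method = "radix")
    outputs <- outputs[ord]
    ids <- ids[ord]
    tools <- lapply(outputs, .align_tool, universe = universe)
    names(tools) <- ids
    roster <- sort(unique(c(unlist(lapply(tools, .tool_donors)),
                            if (!is.null(donorMap)) unname(donorMap))),
                   method = "radix")
    thr <- .DEFAULT_THRESHOLDS[ids]
    names(thr) <- ids
    if (!is.null(toolThresholds))
        thr[names(toolThresholds)] <- toolThresholds
    new("CellAssignmentTable", barcodes = universe, tools = tools,
        donorRoster = roster, toolThresholds = thr)
}

.ensemble_output_columns <- function(toolIds) {
    c("barcode",
      as.vector(rbind(paste0(toolIds, "_label"), paste0(toolIds, "_prob"))),
      "step1_label", "step1_prob", "step2_doublet", "step3_doublet",
      "final_label", "confidence", "status")
}

#' Write the final ensemble output table
#'
#' Writes one TSV row per barcode with a fixed column layout: the barcode,
#' each constituent tool's label and assignment probability (tools in
#' lexicographic order), the Step-1 ensemble label and probability, the
#' Step-2 and Step-3 doublet flags, the final label, the confidence score
#' and the final status. Numeric values are written in full precision, so a
#' write/read round trip is lossless well beyond six decimal places.
#'
#' @param result an [EnsembleResult].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEnsembleOutput()]
#' @export
writeEnsembleOutput <- function(result, path) {
    stopifnot(is(result, "EnsembleResult"))
    tab <- as.data.frame(result@table)
    ids <- result@params$toolIds
    if (is.null(ids))
        ids <- sort(sub("_label$", "",
                        grep("^(?!step1|final)(.*)_label$", colnames(tab),
                             perl = TRUE, value = TRUE)))
    cols <- .ensemble_output_columns(ids)
    miss <- setdiff(cols, colnames(tab))
    if (length(miss))
        stop(sprintf("result table lacks columns: %s", paste(miss, collapse = ", ")))
    out <- tab[, cols, drop = FALSE]
    for (cc in colnames(out))
        if (is.numeric(out[[cc]]))
            out[[cc]] <- sprintf("%.12g", out[[cc]])
    out[out == "NA"] <- "NA"
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(out))
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE, na = "NA")
    invisible(path)
}

#' Read back an ensemble output table
#'
#' Reads a TSV written by [writeEnsembleOutput()] into a data.frame with
#' typed columns (numeric probabilities and confidence, logical doublet
#' flags).
#'
#' @param path path to the TSV.
#' @return a data.frame with one row per barcode.
#' @export
readEnsembleOutput <- function(path) {
    df <- .read_tsv(path)
    for (cc in grep("_prob$|^confidence$", colnames(df), value = TRUE))
        df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    for (cc in grep("_doublet$", colnames(df), value = TRUE))
        df[[cc]] <- as.logical(df[[cc]])
    df
}
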