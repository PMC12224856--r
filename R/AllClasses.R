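#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame DFrame
#' @importFrom stats setNames
NULL

## Reserved label strings. A cell's label is either a donor identifier, or one
## of these two sentinels; donor identifiers may not collide with them.
.DBL <- "doublet"
.UNS <- "unassigned"

.VALID_TOOLS <- c("demuxalot", "demuxlet", "freemuxlet", "souporcell", "vireo")

#' ToolOutput: one constituent demultiplexer's result in a tool-neutral schema
#'
#' Holds, per cell barcode, the call of a single genetic demultiplexing tool
#' (singlet / doublet / unassigned), the assigned donor for singlets, the
#' tool's assignment probability, any doublet-related feature columns the tool
#' reports, and (for tools that publish them) full per-class posterior
#' probabilities.
#'
#' @slot toolId single string, one of `"demuxalot"`, `"demuxlet"`,
#'   `"freemuxlet"`, `"souporcell"`, `"vireo"`.
#' @slot barcode character vector of unique cell barcodes.
#' @slot call character vector aligned to `barcode`: `"singlet"`, `"doublet"`
#'   or `"unassigned"`.
#' @slot donor character vector aligned to `barcode`; the assigned donor for
#'   singlet calls, `NA` otherwise.
#' @slot prob numeric vector of assignment probabilities in `[0, 1]` (`NA`
#'   allowed).
#' @slot features data.frame of numeric feature columns with one row per
#'   barcode (zero columns allowed).
#' @slot classProbs either `NULL` or a numeric matrix with one row per barcode
#'   whose columns are class labels (donor ids, possibly a `"doublet"`
#'   column); used by tools that report full posteriors.
#'
#' @seealso [readVireoDonorIds()], [mergeToolOutputs()]
#' @export
setClass("ToolOutput",
    representation(
        toolId = "character",
        barcode = "character",
        call = "character",
        donor = "character",
        prob = "numeric",
        features = "data.frame",
        classProbs = "ANY"
    ),
    prototype(classProbs = NULL)
)

setValidity("ToolOutput", function(object) {
    msg <- character()
    n <- length(object@barcode)
    if (length(object@toolId) != 1L || !object@toolId %in% .VALID_TOOLS)
        msg <- c(msg, sprintf("toolId must be one of: %s",
                              paste(.VALID_TOOLS, collapse = ", ")))
    if (anyDuplicated(object@barcode))
        msg <- c(msg, "barcodes must be unique within a ToolOutput")
    if (length(object@call) != n || length(object@donor) != n ||
        length(object@prob) != n)
        msg <- c(msg, "call, donor and prob must be aligned to barcode")
    if (!all(object@call %in% c("singlet", .DBL, .UNS)))
        msg <- c(msg, "call must be 'singlet', 'doublet' or 'unassigned'")
    bad <- object@call == "singlet" &
        (is.na(object@donor) | !nzchar(object@donor))
    if (any(bad))
        msg <- c(msg, "singlet calls must carry a non-empty donor id")
    if (any(object@donor %in% c(.DBL, .UNS), na.rm = TRUE))
        msg <- c(msg, "donor ids may not equal the reserved labels 'doublet'/'unassigned'")
    p <- object@prob
    if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "assignment probabilities must lie in [0, 1]")
    if (nrow(object@features) != n && ncol(object@features) > 0L)
        msg <- c(msg, "features must have one row per barcode")
    if (!is.null(object@classProbs)) {
        if (!is.matrix(object@classProbs) || nrow(object@classProbs) != n)
            msg <- c(msg, "classProbs must be a matrix with one row per barcode")
    }
    if (length(msg)) msg else TRUE
})

#' CellAssignmentTable: merged per-barcode record of all constituent tools
#'
#' The merged view of two or more [ToolOutput] objects over a shared barcode
#' universe: every tool's call, donor, probability and features aligned to one
#' ordered barcode vector, plus the donor roster (union of donor ids seen by
#' any tool) and per-tool assignment-probability thresholds.
#'
#' @slot barcodes ordered character vector of unique barcodes.
#' @slot tools named list of [ToolOutput] objects, each aligned to `barcodes`.
#' @slot donorRoster character vector of donor identifiers.
#' @slot toolThresholds named numeric vector of per-tool probability
#'   thresholds in `[0, 1]` used by the confidence score and yield metrics.
#'
#' @seealso [mergeToolOutputs()]
#' @export
setClass("CellAssignmentTable",
    representation(
        barcodes = "character",
        tools = "list",
        donorRoster = "character",
        toolThresholds = "numeric"
    )
)

setValidity("CellAssignmentTable", function(object) {
    msg <- character()
    if (anyDuplicated(object@barcodes))
        msg <- c(msg, "barcodes must be unique")
    ids <- vapply(object@tools, function(t) t@toolId, character(1))
    if (!identical(names(object@tools), unname(ids)))
        msg <- c(msg, "tools list must be named by toolId")
    if (anyDuplicated(ids))
        msg <- c(msg, "each toolId may appear at most once")
    for (t in object@tools) {
        if (!identical(t@barcode, object@barcodes))
            msg <- c(msg, sprintf("tool '%s' is not aligned to the barcode universe", t@toolId))
    }
    if (any(object@donorRoster %in% c(.DBL, .UNS)))
        msg <- c(msg, "donor roster may not contain reserved labels")
    thr <- object@toolThresholds
    if (length(thr) && (is.null(names(thr)) || any(thr < 0 | thr > 1)))
        msg <- c(msg, "toolThresholds must be named and in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' ToolWeights: per-tool balanced-accuracy weights
#'
#' The weight of each constituent tool in the accuracy-weighted ensemble —
#' its balanced accuracy estimated against either the leave-one-tool-out
#' consensus proxy or a supplied ground-truth labelling — together with the
#' number of reference cells each estimate used.
#'
#' @slot weights named numeric vector in `[0, 1]`, one entry per tool.
#' @slot referenceKind `"consensus_proxy"` or `"ground_truth"`.
#' @slot nReference named integer vector: reference cells used per tool.
#'
#' @seealso [estimateToolWeights()]
#' @export
setClass("ToolWeights",
    representation(
        weights = "numeric",
        referenceKind = "character",
        nReference = "integer"
    )
)

setValidity("ToolWeights", function(object) {
    msg <- character()
    w <- object@weights
    if (is.null(names(w)) || any(w < 0 | w > 1, na.rm = TRUE))
        msg <- c(msg, "weights must be named and in [0, 1]")
    if (!object@referenceKind %in% c("consensus_proxy", "ground_truth"))
        msg <- c(msg, "referenceKind must be 'consensus_proxy' or 'ground_truth'")
    if (length(msg)) msg else TRUE
})

#' SweepResult: kurtosis surface of the doublet-detection parameter sweep
#'
#' Records the full (nCD, pT) grid of the graph-based doublet detection
#' sweep: the kurtosis K of the nearest-neighbour frequency (fNN)
#' distribution at every grid point, the fNN tables themselves, and the
#' selected pair.
#'
#' @slot exDR expected doublet rate in (0, 1).
#' @slot grid data.frame with columns `nCD`, `pT`, `K`, `nPutative`
#'   (degenerate grid points carry `K = -Inf`).
#' @slot fnnTables named list (keys `"nCD<k>_pT<p>"`) of named integer
#'   vectors: fNN counts of the putative doublets at each grid point.
#' @slot chosenNCD,chosenPT the selected parameter pair.
#' @slot selectionPath `"inflection"` or `"max_K"`.
#'
#' @seealso [parameterSweep()]
#' @export
setClass("SweepResult",
    representation(
        exDR = "numeric",
        grid = "data.frame",
        fnnTables = "list",
        chosenNCD = "integer",
        chosenPT = "numeric",
        selectionPath = "character"
    )
)

setValidity("SweepResult", function(object) {
    msg <- character()
    if (object@exDR <= 0 || object@exDR >= 1)
        msg <- c(msg, "exDR must lie strictly in (0, 1)")
    if (any(object@grid$pT <= 0 | object@grid$pT >= 1))
        msg <- c(msg, "pT values must lie strictly in (0, 1)")
    key <- paste(object@grid$nCD, object@grid$pT)
    if (!(paste(object@chosenNCD, object@chosenPT) %in% key))
        msg <- c(msg, "chosen (nCD, pT) must be a grid point")
    if (!object@selectionPath %in% c("inflection", "max_K"))
        msg <- c(msg, "selectionPath must be 'inflection' or 'max_K'")
    if (length(msg)) msg else TRUE
})

#' EnsembleResult: final per-cell ensemble assignments
#'
#' The end product of the pipeline: per barcode, every constituent tool's
#' label and probability, the accuracy-weighted ensemble (Step 1) label and
#' probability, the graph-based (Step 2) and ensemble-independent (Step 3)
#' doublet flags, the final label, the singlet confidence score and the final
#' status (`singlet`, `doublet` or `unassigned`). Auxiliary slots carry the
#' tool weights, the per-tool probability calibration (empirical AUC and
#' logistic fit) and the parameter sweep, so a run is self-describing.
#'
#' @slot table an [S4Vectors::DataFrame] with one row per barcode.
#' @slot weights a [ToolWeights].
#' @slot calibration data.frame with one row per tool: `tool`, `auc`,
#'   `intercept`, `slope`, `separation`, `nFit`.
#' @slot sweep a [SweepResult] or `NULL` when Step 2 was disabled.
#' @slot params list echoing the run parameters.
#'
#' @seealso [demultiplexPool()], [writeEnsembleOutput()]
#' @export
setClass("EnsembleResult",
    representation(
        table = "DataFrame",
        weights = "ToolWeights",
        calibration = "data.frame",
        sweep = "ANY",
        params = "list"
    ),
    prototype(sweep = NULL, params = list())
)

setValidity("EnsembleResult", function(object) {
    msg <- character()
    tab <- object@table
    need <- c("barcode", "step1_label", "step1_prob", "step2_doublet",
              "step3_doublet", "final_label", "confidence", "status")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        msg <- c(msg, sprintf("result table lacks columns: %s",
                              paste(miss, collapse = ", ")))
    if (!length(miss)) {
        if (anyDuplicated(tab$barcode))
            msg <- c(msg, "barcodes must be unique in the result table")
        if (!all(tab$status %in% c("singlet", .DBL, .UNS)))
            msg <- c(msg, "status must be singlet/doublet/unassigned")
        if (any((tab$status == .DBL) != (tab$final_label == .DBL)))
            msg <- c(msg, "status 'doublet' must coincide with a doublet final label")
    }
    if (length(msg)) msg else TRUE
})
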