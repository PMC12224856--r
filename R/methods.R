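## Accessors and show() methods.

#' @rdname accessors
#' @export
setMethod("toolId", "ToolOutput", function(x) x@toolId)

#' @rdname accessors
#' @export
setMethod("barcodes", "ToolOutput", function(x) x@barcode)

#' @rdname accessors
#' @export
setMethod("barcodes", "CellAssignmentTable", function(x) x@barcodes)

#' @rdname accessors
#' @export
setMethod("barcodes", "EnsembleResult", function(x) x@table$barcode)

#' @rdname accessors
#' @export
setMethod("toolIds", "CellAssignmentTable", function(x) names(x@tools))

#' @rdname accessors
#' @export
setMethod("donorRoster", "CellAssignmentTable", function(x) x@donorRoster)

#' @rdname accessors
#' @export
setMethod("toolThresholds", "CellAssignmentTable", function(x) x@toolThresholds)

#' @rdname accessors
#' @export
setMethod("getTool", "CellAssignmentTable", function(x, id) {
    if (!id %in% names(x@tools))
        stop(sprintf("tool '%s' is not present in the table", id))
    x@tools[[id]]
})

## Label vector of a ToolOutput: donor id for singlets, sentinel otherwise.
#' @rdname accessors
#' @export
setMethod("cellLabels", "ToolOutput", function(x, ...) {
    lab <- ifelse(x@call == "singlet", x@donor, x@call)
    names(lab) <- x@barcode
    lab
})

#' @rdname accessors
#' @export
setMethod("cellLabels", "EnsembleResult", function(x, ...) {
    lab <- x@table$final_label
    names(lab) <- x@table$barcode
    lab
})

#' @rdname accessors
#' @export
setMethod("resultTable", "EnsembleResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("toolWeights", "EnsembleResult", function(x) x@weights)

setMethod("show", "ToolOutput", function(object) {
    n <- length(object@barcode)
    cat(sprintf("ToolOutput '%s': %d barcodes\n", object@toolId, n))
    tb <- table(factor(object@call, levels = c("singlet", .DBL, .UNS)))
    cat(sprintf("  singlet %d | doublet %d | unassigned %d\n",
                tb[["singlet"]], tb[[.DBL]], tb[[.UNS]]))
    if (ncol(object@features))
        cat("  features:", paste(colnames(object@features), collapse = ", "), "\n")
    if (!is.null(object@classProbs))
        cat(sprintf("  full class posteriors over %d classes\n",
                    ncol(object@classProbs)))
})

setMethod("show", "CellAssignmentTable", function(object) {
    cat(sprintf("CellAssignmentTable: %d barcodes x %d tools (%s)\n",
                length(object@barcodes), length(object@tools),
                paste(names(object@tools), collapse = ", ")))
    cat(sprintf("  donor roster: %d donors\n", length(object@donorRoster)))
})

setMethod("show", "ToolWeights", function(object) {
    cat(sprintf("ToolWeights (%s):\n", object@referenceKind))
    for (id in names(object@weights))
        cat(sprintf("  %-11s w = %.4f  (n_ref = %d)\n", id,
                    object@weights[[id]],
                    if (id %in% names(object@nReference)) object@nReference[[id]] else NA_integer_))
})

setMethod("show", "SweepResult", function(object) {
    cat(sprintf("SweepResult: %d grid points, exDR = %.3f\n",
                nrow(object@grid), object@exDR))
    cat(sprintf("  chosen nCD = %d, pT = %.4f (%s)\n",
                object@chosenNCD, object@chosenPT, object@selectionPath))
})

setMethod("show", "EnsembleResult", function(object) {
    tab <- object@table
    cat(sprintf("EnsembleResult: %d cells\n", nrow(tab)))
    tb <- table(factor(tab$status, levels = c("singlet", .DBL, .UNS)))
    cat(sprintf("  singlet %d | doublet %d | unassigned %d\n",
                tb[["singlet"]], tb[[.DBL]], tb[[.UNS]]))
    cat(sprintf("  step2 doublet flags: %d | step3 doublet flags: %d\n",
                sum(tab$step2_doublet), sum(tab$step3_doublet)))
})
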