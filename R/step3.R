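## Step 3: ensemble-independent doublet rescue.
##
## Certain constituent tools call doublets with very high specificity, but
## the weighted ensemble can still out-vote them. Step 3 therefore accepts
## the doublet calls of nominated tools (Demuxalot and Vireo by default)
## outright. The operation is monotone (the doublet set never shrinks) and
## idempotent.

#' Accept doublet calls from nominated high-specificity tools
#'
#' Any barcode labelled doublet by at least one nominated tool becomes a
#' doublet in the ensemble labelling; all other labels are unchanged. With an
#' empty nomination set the labels are returned untouched.
#'
#' @param labels named character vector of per-cell labels (donor id,
#'   `"doublet"` or `"unassigned"`), covering the table's barcodes.
#' @param table a [CellAssignmentTable].
#' @param nominees tool ids whose doublet calls are accepted; default
#'   `c("demuxalot", "vireo")`. Every nominee must be present in the table.
#' @return list with `labels` (updated vector) and `nConverted` (number of
#'   cells newly turned into doublets).
#' @export
applyIndependentDoublets <- function(labels, table,
                                     nominees = c("demuxalot", "vireo")) {
    miss <- setdiff(nominees, toolIds(table))
    if (length(miss))
        stop(sprintf("nominated tool(s) absent from the table: %s",
                     paste(miss, collapse = ", ")))
    if (!all(barcodes(table) %in% names(labels)))
        stop("labels must cover the table's barcodes")
    if (!length(nominees))
        return(list(labels = labels, nConverted = 0L))
    isDbl <- rep(FALSE, length(barcodes(table)))
    for (id in nominees)
        isDbl <- isDbl | getTool(table, id)@call == .DBL
    hit <- barcodes(table)[isDbl]
    converted <- sum(labels[hit] != .DBL)
    labels[hit] <- .DBL
    list(labels = labels, nConverted = converted)
}

#' Doublet detection specificity
#'
#' `TN / (TN + FP)`, where TN is the number of correctly classified doublets
#' and FP the number of true singlets incorrectly classified as doublets.
#' Useful for auditing, on labelled data, whether a tool is a suitable
#' Step-3 nominee.
#'
#' @param tn,fp non-negative counts.
#' @return specificity in `[0, 1]`.
#' @export
doubletSpecificity <- function(tn, fp) {
    stopifnot(tn >= 0, fp >= 0)
    if (tn + fp == 0)
        stop("doublet specificity undefined: TN + FP is zero")
    tn / (tn + fp)
}
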