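#' Accessor generics
#'
#' Small accessor API over the package's S4 classes: `toolId()` returns the
#' tool identifier of a [ToolOutput]; `barcodes()` the barcode vector of a
#' [ToolOutput], [CellAssignmentTable] or [EnsembleResult]; `toolIds()` the
#' tools present in a table; `donorRoster()` the donor identifiers;
#' `toolThresholds()` the per-tool probability thresholds; `getTool()` one
#' aligned [ToolOutput] from a merged table; `cellLabels()` the per-cell
#' label vector (donor id, `"doublet"` or `"unassigned"`) of a [ToolOutput]
#' or of an [EnsembleResult]'s final assignment; `resultTable()` the full
#' per-cell [S4Vectors::DataFrame] of an [EnsembleResult]; `toolWeights()`
#' the fitted [ToolWeights].
#'
#' @param x the object.
#' @param ... further arguments for methods.
#' @return see the method descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("toolId", function(x) standardGeneric("toolId"))

#' @rdname accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname accessors
#' @export
setGeneric("toolIds", function(x) standardGeneric("toolIds"))

#' @rdname accessors
#' @export
setGeneric("donorRoster", function(x) standardGeneric("donorRoster"))

#' @rdname accessors
#' @export
setGeneric("toolThresholds", function(x) standardGeneric("toolThresholds"))

#' @rdname accessors
#' @export
setGeneric("getTool", function(x, id) standardGeneric("getTool"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x, ...) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("toolWeights", function(x) standardGeneric("toolWeights"))
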