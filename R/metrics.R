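## Evaluation metrics for demultiplexing labels against a reference
## labelling (ground truth, an oligonucleotide proxy, or another tool).
## Undefined quantities (zero denominators) are reported as NA, never as 0.

#' Proportions of correctly classified singlets and doublets
#'
#' A singlet is counted correct when its assigned donor matches the
#' reference donor AND its assignment probability exceeds `threshold`;
#' a doublet is counted correct when both labellings call it a doublet,
#' independent of probability. Also tallies the "ambiguous singlets":
#' correct-donor assignments whose probability fell below the threshold.
#'
#' @param labels named character vector of labels (donor id, `"doublet"`,
#'   `"unassigned"`).
#' @param reference named character vector of reference labels (donor id or
#'   `"doublet"`), over the same barcodes.
#' @param probs named numeric vector of assignment probabilities (`NA`
#'   treated as failing the threshold).
#' @param threshold probability threshold for a confident singlet (default
#'   0: label match only).
#' @return list with `singlet`, `doublet`, `all` proportions (NA when the
#'   reference holds no cells of that kind) and `nAmbiguousCorrect`.
#' @export
proportionCorrect <- function(labels, reference, probs = NULL, threshold = 0) {
    bc <- names(reference)
    labels <- labels[bc]
    if (is.null(probs)) probs <- stats::setNames(rep(1, length(bc)), bc)
    probs <- probs[bc]
    refSng <- reference != .DBL
    match_ <- !is.na(labels) & labels == reference
    confident <- !is.na(probs) & probs > threshold
    tp <- sum(refSng & match_ & confident)
    tn <- sum(!refSng & labels == .DBL, na.rm = TRUE)
    list(singlet = if (sum(refSng)) tp / sum(refSng) else NA_real_,
         doublet = if (sum(!refSng)) tn / sum(!refSng) else NA_real_,
         all = (tp + tn) / length(bc),
         nAmbiguousCorrect = sum(refSng & match_ & !confident))
}

#' Singlet/doublet TP, FP and FN rates against a proxy reference
#'
#' Computes the rates used when a proxy labelling (for example from
#' hashing oligonucleotides) stands in for ground truth. Cells the proxy
#' leaves unassigned must be excluded upstream. The singlet TP (resp. FP)
#' rate is the fraction of proxy singlets that both labellings call singlet
#' with matching (resp. mismatching) donors; the doublet TP rate is the
#' fraction of proxy doublets called doublet; the doublet FP rate divides
#' the proxy singlets called doublet by ALL pooled droplets; and the doublet
#' FN rate is `1 - doublet TP rate`.
#'
#' @param labels named character vector of labels.
#' @param proxy named character vector of proxy labels (donor id or
#'   `"doublet"`).
#' @return list with `singletTP`, `singletFP`, `doubletTP`, `doubletFP`,
#'   `doubletFN` (NA on zero denominators).
#' @export
proxyRates <- function(labels, proxy) {
    proxy <- proxy[proxy != .UNS]
    bc <- names(proxy)
    labels <- labels[bc]
    n <- length(bc)
    proxySng <- proxy != .DBL
    callSng <- !is.na(labels) & labels != .DBL & labels != .UNS
    nPS <- sum(proxySng)
    nPD <- sum(!proxySng)
    dTP <- if (nPD) sum(!proxySng & labels == .DBL, na.rm = TRUE) / nPD else NA_real_
    list(singletTP = if (nPS) sum(proxySng & callSng & labels == proxy) / nPS else NA_real_,
         singletFP = if (nPS) sum(proxySng & callSng & labels != proxy) / nPS else NA_real_,
         doubletTP = dTP,
         doubletFP = if (n) sum(proxySng & labels == .DBL, na.rm = TRUE) / n else NA_real_,
         doubletFN = if (is.na(dTP)) NA_real_ else 1 - dTP)
}

#' Adjusted Rand Index between two labellings
#'
#' The permutation-model chance-corrected Rand index computed from the
#' contingency table of the two labellings. Doublet and unassigned labels
#' are treated as ordinary categories. Identical partitions give 1; the
#' index is invariant to relabelling and symmetric in its arguments.
#'
#' @param a,b vectors of labels over the same items (length >= 2).
#' @return the ARI.
#' @export
adjustedRandIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (length(a) < 2L)
        stop("ARI undefined for fewer than 2 items")
    tab <- table(a, b)
    n <- sum(tab)
    sumnij <- sum(choose(tab, 2))
    sumai <- sum(choose(rowSums(tab), 2))
    sumbj <- sum(choose(colSums(tab), 2))
    expected <- sumai * sumbj / choose(n, 2)
    maxindex <- (sumai + sumbj) / 2
    if (maxindex == expected)
        return(1)  # both partitions trivial
    (sumnij - expected) / (maxindex - expected)
}

#' Matthews correlation coefficient
#'
#' The standard MCC for the binary singlet/doublet classification:
#' `(TN*TP - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any factor
#' under the root is zero the MCC is reported as 0 with a `degenerate`
#' attribute set.
#'
#' @param tp,fn,tn,fp non-negative confusion counts (at least one positive).
#' @return the MCC in `[-1, 1]`.
#' @export
mccScore <- function(tp, fn, tn, fp) {
    stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
    tp <- as.numeric(tp); fn <- as.numeric(fn)
    tn <- as.numeric(tn); fp <- as.numeric(fp)
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (denom == 0) {
        out <- 0
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    (tn * tp - fn * fp) / sqrt(denom)
}

#' Sensitivity and specificity
#'
#' `TP/(TP+FN)` and `TN/(TN+FP)` for the singlet/doublet classification;
#' zero denominators give NA.
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return list with `sensitivity` and `specificity`.
#' @export
sensitivitySpecificity <- function(tp, fn, tn, fp) {
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Usable cells and their error rate
#'
#' Usable cells are singlet calls whose assignment probability exceeds the
#' threshold — the yield available for downstream analysis. With a reference
#' labelling, the error rate among usable cells counts wrong-donor singlets
#' and true doublets classified as singlets.
#'
#' @param labels named character vector of labels.
#' @param probs named numeric vector of assignment probabilities.
#' @param threshold probability threshold.
#' @param reference optional named character reference labelling.
#' @return list with `count` and `errorRate` (NA without reference or when
#'   `count` is 0).
#' @export
usableCells <- function(labels, probs, threshold, reference = NULL) {
    probs <- probs[names(labels)]
    usable <- labels != .DBL & labels != .UNS & !is.na(probs) &
        probs > threshold
    count <- sum(usable)
    err <- NA_real_
    if (!is.null(reference) && count > 0) {
        ref <- reference[names(labels)[usable]]
        lab <- labels[usable]
        bad <- (ref == .DBL) | (ref != .DBL & lab != ref)
        err <- sum(bad, na.rm = TRUE) / count
    }
    list(count = count, errorRate = err)
}

#' Consensus demultiplexing baseline
#'
#' The naive baseline the weighted ensemble is measured against: a cell
#' keeps a donor label only when all four constituent tools assign it to the
#' same donor; cells called ambiguous or doublet by at least one tool are
#' discarded (labelled `"unassigned"`).
#'
#' @param table a [CellAssignmentTable] with 4 tools.
#' @return named character vector of labels.
#' @export
consensusBaseline <- function(table) {
    ids <- toolIds(table)
    if (length(ids) != 4L)
        stop("the consensus baseline requires exactly 4 tools")
    labs <- vapply(ids, function(id) unname(cellLabels(getTool(table, id))),
                   character(length(barcodes(table))))
    agree <- rowSums(labs == labs[, 1L]) == ncol(labs) &
        labs[, 1L] != .UNS & labs[, 1L] != .DBL
    out <- ifelse(agree, labs[, 1L], .UNS)
    stats::setNames(out, barcodes(table))
}

#' AUC of the assignment probability for singlet detection
#'
#' The empirical ROC AUC of the assignment probability as a predictor of
#' correct singlet classification (correct singlets positive, incorrect
#' singlets negative). Returns NA when only one class is present.
#'
#' @param probs numeric vector of probabilities of singlet calls.
#' @param correct logical vector: was the singlet correctly assigned?
#' @return AUC in `[0, 1]`, or NA.
#' @export
aucSingletDetection <- function(probs, correct) {
    keep <- !is.na(probs) & !is.na(correct)
    if (length(unique(correct[keep])) < 2L)
        return(NA_real_)
    empiricalAuc(probs[keep], correct[keep])
}

## Full metric panel of one labelling against a reference.
.metric_row <- function(labels, probs, reference, threshold) {
    bc <- names(reference)
    labels <- labels[bc]
    hasProbs <- !is.null(probs)
    probs <- if (hasProbs) probs[bc] else stats::setNames(rep(NA_real_, length(bc)), bc)
    pc <- proportionCorrect(labels, reference,
                            if (hasProbs) probs else NULL, threshold)
    pr <- proxyRates(labels, reference)
    cc <- .confusion_counts(unname(labels), unname(reference))
    ba <- tryCatch(suppressWarnings(balancedAccuracy(cc$tp, cc$fn, cc$tn, cc$fp)),
                   error = function(e) NA_real_)
    ss <- sensitivitySpecificity(cc$tp, cc$fn, cc$tn, cc$fp)
    dsp <- {
        tnD <- sum(labels == .DBL & reference == .DBL, na.rm = TRUE)
        fpD <- sum(labels == .DBL & reference != .DBL, na.rm = TRUE)
        if (tnD + fpD > 0) tnD / (tnD + fpD) else NA_real_
    }
    sngCalled <- labels != .DBL & labels != .UNS & reference != .DBL
    auc <- aucSingletDetection(probs[sngCalled],
                               labels[sngCalled] == reference[sngCalled])
    uc <- usableCells(labels, probs, threshold, reference)
    data.frame(
        prop_correct_singlets = pc$singlet,
        prop_correct_doublets = pc$doublet,
        prop_correct_all = pc$all,
        n_ambiguous_correct = pc$nAmbiguousCorrect,
        singlet_tp_rate = pr$singletTP,
        singlet_fp_rate = pr$singletFP,
        doublet_tp_rate = pr$doubletTP,
        doublet_fp_rate = pr$doubletFP,
        doublet_fn_rate = pr$doubletFN,
        ari = adjustedRandIndex(unname(labels), unname(reference)),
        balanced_accuracy = ba,
        mcc = as.numeric(mccScore(cc$tp, cc$fn, cc$tn, cc$fp)),
        sensitivity = ss$sensitivity,
        specificity = ss$specificity,
        doublet_specificity = dsp,
        auc_singlet = auc,
        usable_cells = uc$count,
        usable_error_rate = uc$errorRate
    )
}

#' Evaluate every tool, the ensemble, and the consensus baseline
#'
#' Computes the full metric panel (proportions correct, proxy TP/FP/FN
#' rates, ARI, balanced accuracy, MCC, sensitivity, specificity, doublet
#' specificity, singlet-detection AUC, usable-cell yield and error rate) for
#' each constituent tool's labels, the ensemble's final labels, and the
#' all-four-tools consensus baseline, against a reference labelling.
#'
#' @param result an [EnsembleResult].
#' @param table the [CellAssignmentTable] the result was computed from.
#' @param reference named character vector of reference labels (donor id or
#'   `"doublet"`); cells labelled `"unassigned"` in the reference are
#'   excluded.
#' @param confidenceThreshold retention threshold used for the ensemble's
#'   usable-cell yield (default 1.00, on the confidence-score scale).
#' @return data.frame, one row per labelling (`tool` column), in the column
#'   layout of the metric panel.
#' @export
evaluatePool <- function(result, table, reference, confidenceThreshold = 1.00) {
    reference <- reference[reference != .UNS]
    reference <- reference[names(reference) %in% barcodes(table)]
    if (!length(reference))
        stop("no reference cells overlap the table")
    thr <- toolThresholds(table)
    rows <- list()
    for (id in toolIds(table)) {
        t <- getTool(table, id)
        rows[[id]] <- .metric_row(cellLabels(t),
                                  stats::setNames(t@prob, t@barcode),
                                  reference, thr[[id]])
    }
    tab <- resultTable(result)
    finalLabels <- stats::setNames(tab$final_label, tab$barcode)
    conf <- stats::setNames(tab$confidence, tab$barcode)
    rows[["ensemble"]] <- .metric_row(finalLabels, conf, reference,
                                      confidenceThreshold)
    if (length(toolIds(table)) == 4L)
        rows[["consensus_baseline"]] <- .metric_row(consensusBaseline(table),
                                                    NULL, reference, 0)
    out <- do.call(rbind, rows)
    cbind(tool = names(rows), out, row.names = NULL)
}
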