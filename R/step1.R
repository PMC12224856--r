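## Step 1: accuracy-weighted probabilistic ensemble.
##
## Each tool's per-cell class probabilities (over donors + doublet) are
## weighted by the tool's balanced accuracy, estimated on real pools against
## a leave-one-tool-out consensus proxy, and the maximum-probability class is
## assigned per cell.

#' Leave-one-tool-out consensus reference labels
#'
#' For the tool being weighted, returns the cells on which all remaining
#' tools carry an identical non-unassigned label (the same donor, or all
#' doublet). These unanimous cells serve as a proxy for ground truth when
#' estimating the held-out tool's balanced accuracy on pools that lack
#' ground-truth labels.
#'
#' @param table a [CellAssignmentTable] with at least three tools besides the
#'   held-out one (two remaining tools is the hard minimum).
#' @param heldOutTool tool id to hold out.
#' @return named character vector of labels (donor id or `"doublet"`) for the
#'   consensus barcodes only.
#' @export
consensusReference <- function(table, heldOutTool) {
    others <- setdiff(toolIds(table), heldOutTool)
    if (length(others) < 2L)
        stop("need at least two tools besides the held-out tool")
    labs <- vapply(others, function(id) unname(cellLabels(getTool(table, id))),
                   character(length(barcodes(table))))
    ok <- rowSums(labs == labs[, 1L]) == ncol(labs) & labs[, 1L] != .UNS
    stats::setNames(labs[ok, 1L], barcodes(table)[ok])
}

#' Balanced accuracy from singlet/doublet confusion counts
#'
#' Computes `(TP/(TP+FN) + TN/(TN+FP)) / 2`: the mean of the singlet recall
#' (TP = reference singlets assigned the correct donor, FN = reference
#' singlets misclassified — wrong donor or a doublet call) and the doublet
#' recall (TN = reference doublets called doublet, FP = reference doublets
#' called singlet). Averaging the two class-conditional recalls makes the
#' statistic robust to the heavy singlet/doublet imbalance of pooled
#' droplets. When one term's denominator is zero (a reference set with no
#' doublets, or no singlets), that term is dropped and the other returned
#' alone, with a warning.
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balancedAccuracy <- function(tp, fn, tn, fp) {
    stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
    terms <- c(if (tp + fn > 0) tp / (tp + fn),
               if (tn + fp > 0) tn / (tn + fp))
    if (!length(terms))
        stop("balanced accuracy undefined: both denominators are zero")
    if (length(terms) < 2L)
        warning("one balanced-accuracy term has a zero denominator; using the other term alone")
    mean(terms)
}

## Confusion counts of a tool's labels against reference labels, grouped by
## the reference class so that tp/(tp+fn) is the singlet recall (donor match
## required) and tn/(tn+fp) the doublet recall -- the class-conditional
## rates balanced accuracy averages. Unassigned tool calls are excluded
## (they are neither singlet nor doublet calls); reference labels are donor
## ids or "doublet".
.confusion_counts <- function(toolLabels, refLabels) {
    keep <- toolLabels != .UNS
    tl <- toolLabels[keep]
    rl <- refLabels[keep]
    toolSng <- tl != .DBL
    refSng <- rl != .DBL
    list(tp = sum(refSng & toolSng & tl == rl),
         fn = sum(refSng & (!toolSng | tl != rl)),
         tn = sum(!refSng & !toolSng),
         fp = sum(!refSng & toolSng))
}

#' Estimate per-tool balanced-accuracy weights
#'
#' For each tool, builds singlet/doublet confusion counts of its labels
#' against the leave-one-tool-out consensus proxy (or against a supplied
#' ground-truth labelling, for validation runs) and sets the tool's ensemble
#' weight to its balanced accuracy — the mean of its singlet recall (donor
#' match required) and its doublet recall on the reference cells. Because
#' both terms are conditioned on the reference class, the estimate is
#' insensitive to the proxy set's singlet/doublet imbalance. Unassigned tool
#' calls are excluded from the counts. A tool with an empty reference set
#' receives the mean of the other tools' weights, with a warning.
#'
#' @param table a [CellAssignmentTable].
#' @param reference optional named character vector of ground-truth labels
#'   (donor id or `"doublet"`) keyed by barcode.
#' @return a [ToolWeights].
#' @export
estimateToolWeights <- function(table, reference = NULL) {
    ids <- toolIds(table)
    refKind <- if (is.null(reference)) "consensus_proxy" else "ground_truth"
    w <- stats::setNames(rep(NA_real_, length(ids)), ids)
    nref <- stats::setNames(integer(length(ids)), ids)
    for (id in ids) {
        ref <- if (is.null(reference)) consensusReference(table, id) else
            reference[names(reference) %in% barcodes(table)]
        labs <- cellLabels(getTool(table, id))[names(ref)]
        cc <- .confusion_counts(unname(labs), unname(ref))
        nref[[id]] <- length(ref)
        if (length(ref) == 0L || (cc$tp + cc$fn == 0 && cc$tn + cc$fp == 0))
            next
        w[[id]] <- balancedAccuracy(cc$tp, cc$fn, cc$tn, cc$fp)
    }
    if (anyNA(w)) {
        if (all(is.na(w)))
            stop("no tool has a usable reference set; cannot estimate weights")
        warning(sprintf("empty reference set for tool(s) %s; using the mean of the other weights",
                        paste(names(w)[is.na(w)], collapse = ", ")))
        w[is.na(w)] <- mean(w, na.rm = TRUE)
    }
    new("ToolWeights", weights = w, referenceKind = refKind, nReference = nref)
}

#' Per-tool class-probability matrix
#'
#' Expands one tool's calls into a full probability distribution over the
#' classes `donor roster + doublet`, one row per barcode. Tools that publish
#' full per-class posteriors (Demuxalot; Souporcell via its normalised
#' cluster log-probabilities) have them mapped onto the roster and
#' renormalised. Other tools use a point-mass expansion: the assigned donor
#' receives the assignment probability `p`, the doublet class the tool's
#' doublet probability `d` when available (else 0), and the remaining mass
#' `1 - p - d` (floored at 0) is spread uniformly over the other donors. A
#' doublet call puts its probability on the doublet class with the remainder
#' spread over donors; an unassigned call yields the uniform distribution.
#' Cells with `p + d > 1` are clipped and renormalised (one warning reports
#' how many).
#'
#' @param table a [CellAssignmentTable].
#' @param toolId tool present in `table`.
#' @return numeric matrix, rows = barcodes, columns = sorted donor roster
#'   followed by `"doublet"`; rows sum to 1.
#' @export
perToolClassProbs <- function(table, toolId) {
    t <- getTool(table, toolId)
    donors <- sort(donorRoster(table), method = "radix")
    classes <- c(donors, .DBL)
    S <- length(donors)
    n <- length(t@barcode)
    m <- matrix(0, nrow = n, ncol = length(classes),
                dimnames = list(t@barcode, classes))
    dblFeat <- intersect(c("doublet_prob", "prob_doublet"), colnames(t@features))
    d <- if (length(dblFeat)) t@features[[dblFeat[1L]]] else rep(NA_real_, n)
    d[is.na(d)] <- 0
    d <- pmin(pmax(d, 0), 1)
    p <- t@prob
    nClipped <- 0L
    hasFull <- !is.null(t@classProbs)
    rs <- rep(0, n)
    fullAllCalls <- FALSE
    if (hasFull) {
        src <- t@classProbs
        common <- intersect(colnames(src), classes)
        full <- matrix(0, nrow = n, ncol = length(classes),
                       dimnames = list(t@barcode, classes))
        full[, common] <- src[, common]
        full[is.na(full)] <- 0
        rs <- rowSums(full)
        ## tools whose posteriors include a doublet class (Demuxalot) use the
        ## full row for every call; Souporcell's cluster posteriors lack a
        ## doublet class, so its doublet calls fall back to the point mass
        fullAllCalls <- .DBL %in% colnames(src)
    }
    isUns <- t@call == .UNS
    useFull <- hasFull & !isUns & rs > 0 &
        (t@call == "singlet" | fullAllCalls)
    isDblPoint <- !isUns & !useFull & t@call == .DBL
    isSngPoint <- !isUns & !useFull & t@call == "singlet"
    if (any(isUns))
        m[isUns, ] <- 1 / length(classes)
    if (any(useFull))
        m[useFull, ] <- full[useFull, , drop = FALSE] / rs[useFull]
    ## fall back to uniform for degenerate full-posterior singlet rows
    degen <- hasFull & !isUns & !useFull & !isDblPoint & rs <= 0 &
        t@call == "singlet"
    if (any(degen)) {
        m[degen, ] <- 1 / length(classes)
        isSngPoint <- isSngPoint & !degen
    }
    if (any(isDblPoint)) {
        pd <- p[isDblPoint]
        pd[is.na(pd)] <- 1
        m[isDblPoint, .DBL] <- pd
        if (S > 0)
            m[isDblPoint, donors] <- (1 - pd) / S
    }
    if (any(isSngPoint)) {
        ps <- p[isSngPoint]
        ps[is.na(ps)] <- 1
        di <- d[isSngPoint]
        clip <- ps + di > 1 + 1e-6
        nClipped <- sum(clip)
        sc <- ifelse(clip, ps + di, 1)
        ps <- ps / sc
        di <- di / sc
        rows <- which(isSngPoint)
        rest <- pmax(0, 1 - ps - di)
        if (S > 1)
            m[rows, donors] <- rest / (S - 1)
        m[cbind(rows, match(t@donor[rows], classes))] <- ps
        m[rows, .DBL] <- if (S > 1) di else di + rest
    }
    if (nClipped)
        warning(sprintf("tool '%s': %d cell(s) had p + doublet prob > 1; clipped and renormalised",
                        toolId, nClipped))
    m / rowSums(m)
}

#' Accuracy-weighted ensemble of class probabilities
#'
#' Combines the per-tool class-probability matrices into the ensemble
#' distribution: for each cell and class `i`,
#' `p(y = i | E) = sum_j w_j p_j(y = i) / sum_j w_j`. The division by the
#' total weight turns the proportional weighted sum into a proper
#' distribution, so the ensemble probability is exactly 1 when all tools
#' agree with probability 1.
#'
#' @param probs named list of matrices from [perToolClassProbs()], sharing
#'   barcodes and classes.
#' @param weights a [ToolWeights] (or named numeric vector) covering the
#'   tools in `probs`.
#' @return matrix of the same shape; rows sum to 1.
#' @export
weightedEnsemble <- function(probs, weights) {
    if (is(weights, "ToolWeights")) weights <- weights@weights
    stopifnot(length(probs) >= 2L, !is.null(names(probs)))
    w <- weights[names(probs)]
    if (anyNA(w))
        stop("weights missing for some tools in 'probs'")
    if (sum(w) <= 0)
        stop("total tool weight is zero; no informative tool")
    dn <- dimnames(probs[[1L]])
    for (m in probs)
        if (!identical(dimnames(m), dn))
            stop("class-probability matrices must share barcodes and classes")
    acc <- 0
    for (j in seq_along(probs))
        acc <- acc + w[[j]] * probs[[j]]
    acc / sum(w)
}

#' Assign the maximum-probability class per cell
#'
#' Takes the ensemble class-probability matrix and assigns each barcode the
#' class with the largest probability. Ties are broken deterministically:
#' donors in lexicographic order, with the doublet class losing ties to
#' donors (the matrix columns are ordered donors-then-doublet and the first
#' maximum wins).
#'
#' @param ensemble matrix from [weightedEnsemble()].
#' @return data.frame with columns `barcode`, `label`, `prob`.
#' @export
assignStep1 <- function(ensemble) {
    stopifnot(is.matrix(ensemble), nrow(ensemble) > 0L)
    idx <- max.col(ensemble, ties.method = "first")
    data.frame(barcode = rownames(ensemble),
               label = colnames(ensemble)[idx],
               prob = ensemble[cbind(seq_len(nrow(ensemble)), idx)],
               stringsAsFactors = FALSE)
}
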