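## Singlet assignment confidence score.
##
## Each tool's assignment probability is calibrated against the
## leave-one-tool-out consensus proxy: a univariate logistic regression of
## correctness on probability, and the empirical ROC AUC of the probability
## as a predictor of correctness. For each final singlet, if at least one
## tool matches the ensemble label with a probability above that tool's
## threshold, the best such tool's AUC is added to the Step-1 ensemble
## probability; singlets below the retention threshold (default 1.00) are
## reported as unassigned.

#' Logistic regression of singlet correctness on assignment probability
#'
#' Fits `correct ~ prob` by maximum-likelihood logistic regression
#' (IRLS, convergence tolerance 1e-8, at most 100 iterations). With fewer
#' than `minN` observations, a single outcome class, or (quasi-)separation,
#' the fit is skipped and flagged — the AUC, being ranking-based, is
#' unaffected by the monotone fit.
#'
#' @param probs numeric vector of assignment probabilities.
#' @param correct logical vector of the same length.
#' @param minN minimum number of observations for a fit (default 10).
#' @return list with `intercept`, `slope` (NA when skipped), `separation`
#'   (flag) and `nFit`.
#' @export
fitSingletLogit <- function(probs, correct, minN = 10L) {
    stopifnot(length(probs) == length(correct))
    keep <- !is.na(probs) & !is.na(correct)
    probs <- probs[keep]
    correct <- as.logical(correct[keep])
    n <- length(probs)
    skipped <- list(intercept = NA_real_, slope = NA_real_,
                    separation = TRUE, nFit = n)
    if (n < minN || length(unique(correct)) < 2L)
        return(skipped)
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(correct ~ probs, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (sep || !fit$converged)
        return(skipped)
    cf <- stats::coef(fit)
    list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
         separation = FALSE, nFit = n)
}

#' Empirical ROC AUC
#'
#' The empirical area under the ROC curve of `scores` as a predictor of the
#' positive class: the fraction of positive-negative pairs in which the
#' positive scores higher, counting ties as one half (the scaled
#' Mann-Whitney rank-sum statistic). Both classes must be present.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive class).
#' @return AUC in `[0, 1]`.
#' @export
empiricalAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]
    labels <- as.logical(labels[keep])
    nPos <- sum(labels)
    nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L)
        stop("empirical AUC undefined: both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Calibrate each tool's assignment probability against the consensus proxy
#'
#' For every tool in the table, restricts to the cells the leave-one-tool-out
#' consensus proxy calls singlets and on which the tool itself made a singlet
#' call, defines correctness as agreement with the proxy donor, and computes
#' the logistic fit and the empirical AUC of the tool's assignment
#' probability as a predictor of correctness. With ground-truth labels
#' supplied, those replace the proxy.
#'
#' @param table a [CellAssignmentTable].
#' @param reference optional named character vector of ground-truth labels.
#' @param minN minimum observations for the logistic fit.
#' @return data.frame with one row per tool: `tool`, `auc`, `intercept`,
#'   `slope`, `separation`, `nFit`.
#' @export
calibrateTools <- function(table, reference = NULL, minN = 10L) {
    ids <- toolIds(table)
    out <- data.frame(tool = ids, auc = NA_real_, intercept = NA_real_,
                      slope = NA_real_, separation = NA, nFit = 0L,
                      stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
        id <- ids[i]
        ref <- if (is.null(reference)) consensusReference(table, id) else
            reference[names(reference) %in% barcodes(table)]
        ref <- ref[ref != .DBL & ref != .UNS]
        t <- getTool(table, id)
        idx <- match(names(ref), t@barcode)
        sng <- t@call[idx] == "singlet" & !is.na(t@prob[idx])
        probs <- t@prob[idx][sng]
        correct <- t@donor[idx][sng] == unname(ref)[sng]
        if (length(unique(correct)) == 2L)
            out$auc[i] <- empiricalAuc(probs, correct)
        fit <- fitSingletLogit(probs, correct, minN = minN)
        out$intercept[i] <- fit$intercept
        out$slope[i] <- fit$slope
        out$separation[i] <- fit$separation
        out$nFit[i] <- fit$nFit
    }
    out
}

#' Singlet confidence scores and final retention status
#'
#' For each cell whose final label is a donor, finds the constituent tools
#' whose own label matches the final label and whose assignment probability
#' exceeds that tool's threshold. When at least one such tool exists, the
#' confidence score is the Step-1 ensemble probability plus the largest AUC
#' among the matching confident tools; otherwise it is the ensemble
#' probability alone. Singlets whose confidence falls below the retention
#' threshold are reported as unassigned; doublets bypass scoring.
#'
#' @param labels named character vector of final per-cell labels.
#' @param step1Prob named numeric vector of Step-1 ensemble probabilities.
#' @param calibration data.frame from [calibrateTools()].
#' @param table a [CellAssignmentTable].
#' @param threshold retention threshold (default 1.00).
#' @return data.frame with columns `barcode`, `confidence`, `status`.
#' @export
confidenceScores <- function(labels, step1Prob, calibration, table,
                             threshold = 1.00) {
    bcs <- barcodes(table)
    labels <- labels[bcs]
    conf <- rep(NA_real_, length(bcs))
    status <- rep(.UNS, length(bcs))
    isDbl <- labels == .DBL
    isSng <- !isDbl & labels != .UNS
    status[isDbl] <- .DBL
    auc <- stats::setNames(calibration$auc, calibration$tool)
    thr <- toolThresholds(table)
    bestAuc <- rep(-Inf, length(bcs))
    for (id in toolIds(table)) {
        if (is.na(auc[[id]])) next
        t <- getTool(table, id)
        match_ <- t@call == "singlet" & !is.na(t@prob) &
            t@donor == labels & t@prob > thr[[id]]
        match_[is.na(match_)] <- FALSE
        bestAuc[match_] <- pmax(bestAuc[match_], auc[[id]])
    }
    p1 <- step1Prob[bcs]
    conf[isSng] <- p1[isSng] + ifelse(is.finite(bestAuc[isSng]),
                                      bestAuc[isSng], 0)
    status[isSng & conf >= threshold] <- "singlet"
    data.frame(barcode = bcs, confidence = conf, status = status,
               stringsAsFactors = FALSE)
}
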