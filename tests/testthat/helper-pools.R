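# Shared fixture builders: hand-built ToolOutput objects and small synthetic
# pools used across the test files.

# A ToolOutput from label strings ("donorX", "doublet", "unassigned").
makeToolOutput <- function(id, barcode, labels, probs = NULL,
                           features = NULL, classProbs = NULL) {
    call <- ifelse(labels == "doublet", "doublet",
                   ifelse(labels == "unassigned", "unassigned", "singlet"))
    donor <- ifelse(call == "singlet", labels, NA_character_)
    if (is.null(probs)) probs <- rep(0.95, length(barcode))
    if (is.null(features))
        features <- data.frame(row.names = seq_along(barcode))[, 0]
    new("ToolOutput", toolId = id, barcode = barcode, call = call,
        donor = donor, prob = probs, features = features,
        classProbs = classProbs)
}

# A 4-tool table over a shared barcode set from a label matrix
# (rows = barcodes, columns = tools).
makeTable <- function(labelMatrix, probs = NULL) {
    bcs <- rownames(labelMatrix)
    outs <- lapply(colnames(labelMatrix), function(id)
        makeToolOutput(id, bcs, labelMatrix[, id],
                       probs = if (is.null(probs)) NULL else probs[, id]))
    mergeToolOutputs(outs)
}

# Default 4-tool synthetic pool, small enough for fast tests.
smallPool <- function(seed = 1L, nCells = 600L, nDonors = 6L,
                      doubletRate = 0.15, ...) {
    simulatePool(syntheticPoolSpec(nCells, nDonors,
                                   doubletRate = doubletRate,
                                   seed = seed, ...))
}

# Tool profiles with the given singlet accuracies (order: demuxalot,
# demuxlet, souporcell, vireo), other rates at the package defaults.
profilesWithAccuracies <- function(acc) {
    prof <- defaultToolProfiles()
    for (i in seq_along(prof)) prof[[i]]$singletAccuracy <- acc[i]
    prof
}

# Independent oracle: balanced accuracy of one tool's labels against a
# reference labelling, by explicit counting loops (mean of singlet recall
# with donor match and doublet recall; unassigned tool calls skipped).
oracleBalancedAccuracy <- function(toolLabels, refLabels) {
    tp <- fn <- tn <- fp <- 0
    for (i in seq_along(refLabels)) {
        tl <- toolLabels[i]; rl <- refLabels[i]
        if (tl == "unassigned") next
        if (rl == "doublet") {
            if (tl == "doublet") tn <- tn + 1 else fp <- fp + 1
        } else {
            if (tl == rl) tp <- tp + 1 else fn <- fn + 1
        }
    }
    terms <- c(if (tp + fn > 0) tp / (tp + fn), if (tn + fp > 0) tn / (tn + fp))
    mean(terms)
}

# Fraction of true singlets assigned the correct donor label.
singletAccuracyOf <- function(labels, truth) {
    sng <- truth != "doublet"
    mean(labels[names(truth)[sng]] == truth[sng])
}
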