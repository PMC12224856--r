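# Accuracy-weighted probabilistic ensemble: consensus proxy, balanced
# accuracy, class-probability expansion, weighted combination, argmax.

test_that("consensus reference keeps only unanimous non-unassigned cells", {
    labs <- rbind(BC1 = c(demuxalot = "donorA", demuxlet = "donorA",
                          souporcell = "donorA", vireo = "donorB"),
                  BC2 = c("donorA", "donorA", "donorB", "donorA"),
                  BC3 = c("doublet", "doublet", "doublet", "donorA"),
                  BC4 = c("donorB", "donorB", "unassigned", "donorB"))
    tab <- makeTable(labs)
    ref <- consensusReference(tab, "vireo")
    expect_identical(ref, c(BC1 = "donorA", BC3 = "doublet"))
    # the held-out tool's own labels never enter the consensus: with
    # souporcell (the BC2 dissenter) held out, the others are unanimous
    ref2 <- consensusReference(tab, "souporcell")
    expect_identical(unname(ref2["BC2"]), "donorA")
    expect_error(consensusReference(
        mergeToolOutputs(list(
            makeToolOutput("vireo", "BC1", "donorA"),
            makeToolOutput("demuxlet", "BC1", "donorA"))), "vireo"),
        "at least two tools")
})

test_that("balanced accuracy matches hand computation and edge cases", {
    expect_equal(balancedAccuracy(tp = 90, fn = 10, tn = 80, fp = 20), 0.85)
    expect_equal(balancedAccuracy(5, 0, 7, 0), 1.0)
    expect_equal(balancedAccuracy(50, 50, 50, 50), 0.5)
    # a zero denominator drops that term with a warning
    expect_warning(ba <- balancedAccuracy(90, 10, 0, 0), "zero denominator")
    expect_equal(ba, 0.9)
    expect_error(balancedAccuracy(0, 0, 0, 0), "undefined")
})

test_that("estimated weights equal oracle balanced accuracies against truth", {
    pool <- smallPool(seed = 5, nCells = 800, nDonors = 6)
    tab <- poolAssignmentTable(pool)
    w <- estimateToolWeights(tab, reference = pool$truth)
    expect_identical(w@referenceKind, "ground_truth")
    for (id in toolIds(tab)) {
        lab <- cellLabels(getTool(tab, id))
        expect_equal(w@weights[[id]],
                     oracleBalancedAccuracy(unname(lab), unname(pool$truth[names(lab)])),
                     tolerance = 1e-12)
    }
})

test_that("a tool agreeing with the consensus on every reference cell gets weight 1", {
    labs <- matrix("donorA", nrow = 6, ncol = 4,
                   dimnames = list(paste0("BC", 1:6),
                                   c("demuxalot", "demuxlet", "souporcell", "vireo")))
    labs[5:6, ] <- "doublet"
    tab <- makeTable(labs)
    w <- estimateToolWeights(tab)
    expect_true(all(w@weights == 1))
})

test_that("a label-inverting tool is strongly down-weighted", {
    # two donors; vireo systematically swaps them
    set.seed(1)
    n <- 200
    truthDonor <- sample(c("donorA", "donorB"), n, replace = TRUE)
    bcs <- sprintf("BC%03d", seq_len(n))
    swap <- c(donorA = "donorB", donorB = "donorA")
    labs <- cbind(demuxalot = truthDonor, demuxlet = truthDonor,
                  souporcell = truthDonor, vireo = unname(swap[truthDonor]))
    rownames(labs) <- bcs
    tab <- makeTable(labs)
    truth <- stats::setNames(truthDonor, bcs)
    w <- suppressWarnings(estimateToolWeights(tab, reference = truth))@weights
    # singlet recall is exactly 0; no doublets exist so only that term counts
    expect_equal(unname(w[["vireo"]]), 0)
    expect_equal(unname(w[["demuxlet"]]), 1)
    # under the consensus proxy the inverter still ranks strictly last
    wc <- suppressWarnings(estimateToolWeights(tab))@weights
    expect_lte(unname(wc[["vireo"]]), min(wc[c("demuxalot", "demuxlet", "souporcell")]))
})

test_that("point-mass class expansion matches hand arithmetic", {
    t <- new("ToolOutput", toolId = "vireo", barcode = "BC1",
             call = "singlet", donor = "donorB", prob = 0.97,
             features = data.frame(prob_doublet = 0.01,
                                   doublet_logLikRatio = 0))
    u <- makeToolOutput("demuxlet", "BC1", "unassigned")
    tab <- mergeToolOutputs(list(t, u))
    tab@donorRoster <- c("donorA", "donorB", "donorC")
    m <- perToolClassProbs(tab, "vireo")
    expect_equal(unname(m["BC1", ]), c(0.01, 0.97, 0.01, 0.01),
                 tolerance = 1e-12)
    expect_identical(colnames(m), c("donorA", "donorB", "donorC", "doublet"))
    # unassigned expands to the uniform distribution over all classes
    mu <- perToolClassProbs(tab, "demuxlet")
    expect_equal(unname(mu["BC1", ]), rep(0.25, 4))
})

test_that("full posteriors pass through renormalisation unchanged", {
    cp <- matrix(c(0.9, 0.05, 0.05,
                   0.1, 0.1, 0.8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("BC1", "BC2"),
                                 c("donorA", "donorB", "doublet")))
    t <- makeToolOutput("demuxalot", c("BC1", "BC2"), c("donorA", "doublet"),
                        probs = c(0.9, 0.1), classProbs = cp)
    o <- makeToolOutput("vireo", c("BC1", "BC2"), c("donorA", "donorB"))
    tab <- mergeToolOutputs(list(t, o))
    m <- perToolClassProbs(tab, "demuxalot")
    expect_equal(m[, c("donorA", "donorB", "doublet")], cp, tolerance = 1e-12)
})

test_that("rows of every class-probability matrix sum to one", {
    pool <- smallPool(seed = 9, nCells = 300)
    tab <- poolAssignmentTable(pool)
    for (id in toolIds(tab)) {
        m <- suppressWarnings(perToolClassProbs(tab, id))
        expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
        expect_true(all(m >= 0))
    }
})

test_that("weighted ensemble equals a brute-force loop oracle", {
    set.seed(42)
    bcs <- paste0("BC", 1:5)
    classes <- c("donorA", "donorB", "doublet")
    tools <- c("demuxalot", "demuxlet", "souporcell", "vireo")
    probs <- lapply(tools, function(id) {
        m <- matrix(stats::rexp(15), nrow = 5, dimnames = list(bcs, classes))
        m / rowSums(m)
    })
    names(probs) <- tools
    w <- stats::setNames(c(0.91, 0.83, 0.77, 0.88), tools)
    ens <- weightedEnsemble(probs, w)
    # independent oracle: explicit triple loop over cells, classes, tools
    for (i in seq_along(bcs)) for (k in seq_along(classes)) {
        num <- 0
        for (j in tools) num <- num + w[[j]] * probs[[j]][i, k]
        expect_equal(ens[i, k], num / sum(w), tolerance = 1e-12)
    }
    expect_equal(unname(rowSums(ens)), rep(1, 5), tolerance = 1e-12)
})

test_that("weighted ensemble worked examples and degenerate weights", {
    bcs <- "BC1"
    classes <- c("donorA", "donorB", "doublet")
    pa <- matrix(c(1, 0, 0), 1, dimnames = list(bcs, classes))
    pb <- matrix(c(0, 1, 0), 1, dimnames = list(bcs, classes))
    ens <- weightedEnsemble(list(vireo = pa, demuxlet = pb),
                            c(vireo = 0.8, demuxlet = 0.6))
    expect_equal(unname(ens[1, ]), c(0.8 / 1.4, 0.6 / 1.4, 0),
                 tolerance = 1e-12)
    # identical inputs are a fixed point under any weights
    same <- matrix(c(0.2, 0.5, 0.3), 1, dimnames = list(bcs, classes))
    ens2 <- weightedEnsemble(list(vireo = same, demuxlet = same),
                             c(vireo = 0.9, demuxlet = 0.1))
    expect_equal(ens2, same, tolerance = 1e-12)
    expect_error(weightedEnsemble(list(vireo = pa, demuxlet = pb),
                                  c(vireo = 0, demuxlet = 0)),
                 "zero")
})

test_that("raising a tool's weight never lowers its voted class (monotonicity)", {
    set.seed(7)
    bcs <- paste0("BC", 1:20)
    classes <- c("donorA", "donorB", "donorC", "doublet")
    mk <- function() {
        m <- matrix(stats::rexp(80), 20, dimnames = list(bcs, classes))
        m / rowSums(m)
    }
    probs <- list(demuxalot = mk(), demuxlet = mk(), vireo = mk())
    # vireo votes donorA with certainty on every cell
    probs$vireo[] <- 0
    probs$vireo[, "donorA"] <- 1
    for (wv in c(0.2, 0.5, 0.9)) {
        lo <- weightedEnsemble(probs, c(demuxalot = 0.8, demuxlet = 0.7, vireo = wv))
        hi <- weightedEnsemble(probs, c(demuxalot = 0.8, demuxlet = 0.7, vireo = wv + 0.05))
        expect_true(all(hi[, "donorA"] >= lo[, "donorA"] - 1e-12))
    }
})

test_that("argmax assignment breaks ties lexicographically with doublet losing", {
    classes <- c("donorA", "donorB", "doublet")
    m <- matrix(c(0.8 / 1.4, 0.6 / 1.4, 0,
                  0.5, 0.5, 0,
                  0.5, 0, 0.5), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("BC", 1:3), classes))
    a <- assignStep1(m)
    expect_identical(a$label, c("donorA", "donorA", "donorA"))
    expect_equal(a$prob[1], 0.8 / 1.4, tolerance = 1e-12)
    expect_equal(a$prob[2], 0.5)
})

test_that("permuting tool order leaves Step-1 output bit-identical", {
    pool <- smallPool(seed = 13, nCells = 250)
    t1 <- mergeToolOutputs(pool$toolOutputs)
    t2 <- mergeToolOutputs(pool$toolOutputs[c(3, 1, 4, 2)])
    r1 <- suppressWarnings(demultiplexPool(t1, step2 = FALSE, step3 = FALSE))
    r2 <- suppressWarnings(demultiplexPool(t2, step2 = FALSE, step3 = FALSE))
    expect_identical(as.data.frame(resultTable(r1)), as.data.frame(resultTable(r2)))
})
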