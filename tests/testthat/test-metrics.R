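# Evaluation metric suite against reference labellings.

test_that("proportion correct applies the threshold to singlets only", {
    ref <- c(BC1 = "donorA", BC2 = "donorB", BC3 = "doublet", BC4 = "doublet")
    labels <- c(BC1 = "donorA", BC2 = "donorB", BC3 = "doublet", BC4 = "doublet")
    probs <- c(BC1 = 0.99, BC2 = 0.99, BC3 = 0.2, BC4 = 0.1)
    pc <- proportionCorrect(labels, ref, probs, threshold = 0.9)
    expect_equal(pc$singlet, 1)
    expect_equal(pc$doublet, 1)
    expect_equal(pc$all, 1)
    # correct donor below threshold: incorrect for the proportion, but
    # tallied as an ambiguous singlet
    probs["BC2"] <- 0.5
    pc2 <- proportionCorrect(labels, ref, probs, threshold = 0.9)
    expect_equal(pc2$singlet, 0.5)
    expect_identical(pc2$nAmbiguousCorrect, 1L)
    # 10 true doublets, 7 called: 0.7, probability ignored
    ref3 <- stats::setNames(rep("doublet", 10), paste0("D", 1:10))
    lab3 <- stats::setNames(c(rep("doublet", 7), rep("donorA", 3)), names(ref3))
    expect_equal(proportionCorrect(lab3, ref3)$doublet, 0.7)
    # no true singlets: singlet proportion is NA, not 0
    expect_true(is.na(proportionCorrect(lab3, ref3)$singlet))
})

test_that("proxy rates follow their stated denominators and the FN identity", {
    proxy <- c(S1 = "donorA", S2 = "donorB", S3 = "donorC", S4 = "donorD",
               D1 = "doublet")
    # one proxy singlet called doublet: doublet FP = 1 / 5 pooled droplets
    labels <- c(S1 = "donorA", S2 = "donorB", S3 = "donorC", S4 = "doublet",
                D1 = "doublet")
    r <- proxyRates(labels, proxy)
    expect_equal(r$doubletFP, 1 / 5)
    expect_equal(r$singletTP, 3 / 4)
    expect_equal(r$singletFP, 0)
    expect_equal(r$doubletTP, 1)
    expect_equal(r$doubletFN, 0)
    # identical labellings
    r0 <- proxyRates(proxy, proxy)
    expect_equal(unlist(r0), c(singletTP = 1, singletFP = 0, doubletTP = 1,
                               doubletFP = 0, doubletFN = 0))
    # all proxy doublets called singlets
    labels2 <- c(S1 = "donorA", S2 = "donorB", S3 = "donorC", S4 = "donorD",
                 D1 = "donorA")
    r2 <- proxyRates(labels2, proxy)
    expect_equal(r2$doubletTP, 0)
    expect_equal(r2$doubletFN, 1)
})

test_that("the doublet FN identity holds in every full report", {
    pool <- smallPool(seed = 51, nCells = 400, nDonors = 5)
    tab <- poolAssignmentTable(pool)
    res <- suppressWarnings(demultiplexPool(tab, step2 = FALSE, step3 = FALSE))
    m <- evaluatePool(res, tab, pool$truth)
    ok <- !is.na(m$doublet_tp_rate)
    expect_equal(m$doublet_fn_rate[ok], 1 - m$doublet_tp_rate[ok],
                 tolerance = 1e-12)
})

test_that("ARI matches hand computation, permutation invariance and symmetry", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
    set.seed(2)
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(letters[1:4], 60, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
    perm <- c(a = "w", b = "x", c = "y", d = "z")
    expect_equal(adjustedRandIndex(a, b),
                 adjustedRandIndex(unname(perm[a]), b), tolerance = 1e-12)
    expect_error(adjustedRandIndex("x", "y"), "fewer than 2")
})

test_that("ARI agrees with the independent mclust implementation", {
    skip_if_not_installed("mclust")
    set.seed(14)
    for (i in 1:10) {
        a <- sample(c(paste0("donor", 1:5), "doublet"), 200, replace = TRUE)
        b <- sample(c(paste0("donor", 1:5), "doublet"), 200, replace = TRUE)
        expect_equal(adjustedRandIndex(a, b),
                     mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
})

test_that("MCC matches its closed form and stays within [-1, 1]", {
    expect_equal(as.numeric(mccScore(tp = 90, fn = 10, tn = 80, fp = 20)),
                 0.7035264707, tolerance = 1e-9)
    expect_equal(as.numeric(mccScore(50, 0, 50, 0)), 1)
    expect_equal(as.numeric(mccScore(25, 25, 25, 25)), 0)
    degen <- mccScore(10, 5, 0, 0)
    expect_equal(as.numeric(degen), 0)
    expect_true(isTRUE(attr(degen, "degenerate")))
    set.seed(6)
    for (i in 1:200) {
        cc <- as.list(stats::rpois(4, 20))
        names(cc) <- c("tp", "fn", "tn", "fp")
        v <- as.numeric(do.call(mccScore, cc))
        expect_true(v >= -1 - 1e-12 && v <= 1 + 1e-12)
        # brute-force direct evaluation
        denom <- prod(cc$tp + cc$fp, cc$tp + cc$fn, cc$tn + cc$fp, cc$tn + cc$fn)
        if (denom > 0)
            expect_equal(v, (cc$tn * cc$tp - cc$fn * cc$fp) / sqrt(denom),
                         tolerance = 1e-12)
    }
})

test_that("sensitivity and specificity read off the confusion counts", {
    expect_equal(sensitivitySpecificity(90, 10, 80, 20),
                 list(sensitivity = 0.9, specificity = 0.8))
    expect_equal(sensitivitySpecificity(5, 0, 5, 0),
                 list(sensitivity = 1, specificity = 1))
    expect_true(is.na(sensitivitySpecificity(0, 0, 3, 1)$sensitivity))
    expect_equal(sensitivitySpecificity(1, 1, 0, 10)$specificity, 0)
})

test_that("usable cells count confident singlets and their error rate", {
    n <- 100
    bcs <- sprintf("BC%03d", 1:n)
    labels <- stats::setNames(rep("donorA", n), bcs)
    probs <- stats::setNames(rep(0.99, n), bcs)
    ref <- stats::setNames(rep("donorA", n), bcs)
    # 4 wrong-donor singlets + 2 true doublets among 100 usable -> 0.06
    ref[1:4] <- "donorB"
    ref[5:6] <- "doublet"
    uc <- usableCells(labels, probs, 0.9, ref)
    expect_identical(uc$count, 100L)
    expect_equal(uc$errorRate, 0.06)
    # without a reference the count is still reported
    uc2 <- usableCells(labels, probs, 0.9)
    expect_identical(uc2$count, 100L)
    expect_true(is.na(uc2$errorRate))
    probs[] <- 0.5
    expect_identical(usableCells(labels, probs, 0.9, ref)$count, 0L)
})

test_that("the consensus baseline keeps only four-way donor agreement", {
    labs <- rbind(BC1 = c(demuxalot = "donorA", demuxlet = "donorA",
                          souporcell = "donorA", vireo = "donorA"),
                  BC2 = c("donorA", "donorA", "donorA", "doublet"),
                  BC3 = c("donorA", "donorA", "donorB", "donorA"),
                  BC4 = c("donorB", "donorB", "donorB", "unassigned"))
    tab <- makeTable(labs)
    cb <- consensusBaseline(tab)
    expect_identical(unname(cb), c("donorA", "unassigned", "unassigned",
                                   "unassigned"))
})

test_that("metric implementations agree with brute-force counting loops", {
    set.seed(77)
    n <- 800
    bcs <- sprintf("BC%04d", 1:n)
    classes <- c(paste0("donor", 1:6), "doublet")
    ref <- stats::setNames(sample(classes, n, replace = TRUE,
                                  prob = c(rep(0.14, 6), 0.16)), bcs)
    labels <- stats::setNames(sample(c(classes, "unassigned"), n,
                                     replace = TRUE), bcs)
    probs <- stats::setNames(stats::runif(n), bcs)
    thr <- 0.5
    # explicit loops
    nTS <- nTD <- tp <- tn <- amb <- 0
    for (i in seq_len(n)) {
        if (ref[i] == "doublet") {
            nTD <- nTD + 1
            if (labels[i] == "doublet") tn <- tn + 1
        } else {
            nTS <- nTS + 1
            if (labels[i] == ref[i]) {
                if (probs[i] > thr) tp <- tp + 1 else amb <- amb + 1
            }
        }
    }
    pc <- proportionCorrect(labels, ref, probs, thr)
    expect_equal(pc$singlet, tp / nTS, tolerance = 1e-12)
    expect_equal(pc$doublet, tn / nTD, tolerance = 1e-12)
    expect_equal(pc$all, (tp + tn) / n, tolerance = 1e-12)
    expect_identical(pc$nAmbiguousCorrect, as.integer(amb))
    # balanced accuracy via the independent oracle loop
    expect_equal(suppressWarnings(balancedAccuracy(
        tp = sum(labels != "unassigned" & ref != "doublet" & labels == ref),
        fn = sum(labels != "unassigned" & ref != "doublet" & labels != ref),
        tn = sum(labels != "unassigned" & ref == "doublet" & labels == "doublet"),
        fp = sum(labels != "unassigned" & ref == "doublet" &
                 labels != "doublet"))),
        oracleBalancedAccuracy(unname(labels), unname(ref)), tolerance = 1e-12)
})

test_that("singlet-detection AUC delegates to the empirical AUC", {
    expect_equal(aucSingletDetection(c(0.9, 0.8, 0.4, 0.3),
                                     c(TRUE, FALSE, TRUE, FALSE)), 0.75)
    expect_equal(aucSingletDetection(rep(0.5, 10),
                                     rep(c(TRUE, FALSE), 5)), 0.5)
    expect_true(is.na(aucSingletDetection(stats::runif(5), rep(TRUE, 5))))
})
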