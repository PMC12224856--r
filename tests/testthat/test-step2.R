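# Graph-based doublet detection: percentile ranks, confident-doublet screen,
# PCA embedding, nearest-neighbour frequencies, kurtosis and the sweep.

test_that("percentile ranks match hand computation and are tie-averaged", {
    expect_equal(percentileRank(c(1, 2, 3, 4), +1), c(25, 50, 75, 100))
    expect_equal(percentileRank(c(1, 2, 3, 4), -1), c(100, 75, 50, 25))
    # tied pair in n = 2: average of positions 1 and 2 -> 1.5/2 * 100
    expect_equal(suppressWarnings(percentileRank(c(5, 5), +1)), c(75, 75))
    # a constant vector is uninformative: tie-averaged midpoint, warned
    expect_warning(r <- percentileRank(c(2, 2, 2), +1), "identical")
    expect_equal(r, rep(100 * 2 / 3, 3))
})

test_that("percentile ranks are invariant under strictly monotone transforms", {
    set.seed(3)
    x <- stats::rnorm(50)
    for (f in list(function(v) exp(v), function(v) v^3, function(v) 5 * v + 2))
        expect_equal(percentileRank(f(x), +1), percentileRank(x, +1))
    # a decreasing transform with flipped orientation is also identical
    expect_equal(percentileRank(-x, -1), percentileRank(x, +1))
})

test_that("confident-doublet screen matches a brute-force threshold walk", {
    set.seed(11)
    n <- 10
    ranks <- cbind(f1 = percentileRank(stats::rnorm(n)),
                   f2 = percentileRank(stats::rnorm(n)),
                   f3 = percentileRank(stats::rnorm(n)))
    rownames(ranks) <- sprintf("BC%02d", 1:n)
    bruteForce <- function(ranks, nCD) {
        for (t in seq(99.99, 0, by = -0.01)) {
            qual <- rownames(ranks)[apply(ranks > t, 1, all)]
            if (length(qual) >= nCD) return(sort(qual))
        }
        sort(rownames(ranks)[apply(ranks > 0, 1, all)])
    }
    for (nCD in c(1, 2, 3, 5, 10))
        expect_identical(sort(as.vector(findConfidentDoublets(ranks, nCD))),
                         bruteForce(ranks, nCD))
})

test_that("a strictly dominant cell is the first confident doublet", {
    ranks <- cbind(f1 = c(100, 50, 25, 75), f2 = c(100, 75, 50, 25),
                   f3 = c(100, 25, 75, 50))
    rownames(ranks) <- paste0("BC", 1:4)
    cd <- findConfidentDoublets(ranks, 1)
    expect_identical(as.vector(cd)[1], "BC1")
    expect_identical(length(as.vector(cd)), 1L)
    # nCD larger than the pool returns everything with a warning
    expect_warning(all4 <- findConfidentDoublets(ranks, 10), "exceeds")
    expect_identical(length(as.vector(all4)), 4L)
})

test_that("PCA embedding matches the analytic 2x2 eigenproblem", {
    # 3 cells, 2 features; z-scored columns have correlation r, so the
    # covariance eigenvalues are 1+r and 1-r with eigenvectors (1,1)/sqrt 2
    # and (1,-1)/sqrt 2
    x <- matrix(c(1, 2, 4,
                  2, 3, 8), ncol = 2,
                dimnames = list(paste0("BC", 1:3), c("f1", "f2")))
    z <- scale(x)
    r <- stats::cor(z[, 1], z[, 2])
    s <- pcaEmbed(x)
    expected1 <- (z[, 1] + z[, 2]) / sqrt(2)
    expect_equal(unname(s[, "PC1"]), unname(expected1), tolerance = 1e-12)
    ve <- attr(s, "varExplained")
    expect_equal(ve[1], (1 + r) / 2, tolerance = 1e-12)
    # perfectly correlated features: PC1 carries all variance
    y <- cbind(f1 = c(1, 2, 3, 5), f2 = c(2, 4, 6, 10))
    rownames(y) <- paste0("BC", 1:4)
    sy <- pcaEmbed(y)
    expect_equal(max(abs(sy[, "PC2"])), 0, tolerance = 1e-9)
    expect_equal(attr(sy, "varExplained")[1], 1, tolerance = 1e-12)
    # zero-variance features are dropped with a warning
    expect_warning(pcaEmbed(cbind(y, f3 = rep(1, 4))), "zero-variance")
})

test_that("fNN tables equal an O(n^2) brute-force double loop exactly", {
    set.seed(21)
    for (n in c(40, 120, 200)) {
        coords <- matrix(stats::rnorm(2 * n), ncol = 2,
                         dimnames = list(sprintf("BC%03d", 1:n), c("PC1", "PC2")))
        confident <- rownames(coords)[sample(n, 8)]
        for (pT in c(0.5, 0.8, 0.95)) {
            fnn <- neighborFrequency(coords, confident, pT)
            # oracle: explicit double loop over confident doublets and cells
            counts <- stats::setNames(integer(n), rownames(coords))
            for (d in confident) {
                dist <- sqrt(rowSums((coords - matrix(coords[d, ], n, 2,
                                                      byrow = TRUE))^2))
                others <- setdiff(rownames(coords), d)
                pr <- 100 * rank(-dist[others], ties.method = "average") / (n - 1)
                nb <- others[pr > 100 * pT]
                counts[nb] <- counts[nb] + 1L
            }
            counts <- counts[counts >= 1]
            expect_identical(fnn, counts[order(names(counts))])
            expect_true(all(fnn <= length(confident)))
        }
    }
})

test_that("lowering pT never decreases any cell's fNN", {
    set.seed(8)
    coords <- matrix(stats::rnorm(160), ncol = 2,
                     dimnames = list(sprintf("BC%03d", 1:80), c("PC1", "PC2")))
    confident <- rownames(coords)[1:6]
    strict <- neighborFrequency(coords, confident, 0.9)
    loose <- neighborFrequency(coords, confident, 0.6)
    expect_true(all(names(strict) %in% names(loose)))
    expect_true(all(loose[names(strict)] >= strict))
})

test_that("a cell closest to every confident doublet reaches fNN = nCD", {
    # BC1-BC4 confident doublets at the corners; BC5 in the centre is the
    # nearest neighbour of each; BC6 far away never is
    coords <- rbind(BC1 = c(1, 1), BC2 = c(-1, 1), BC3 = c(1, -1),
                    BC4 = c(-1, -1), BC5 = c(0, 0), BC6 = c(50, 50))
    colnames(coords) <- c("PC1", "PC2")
    fnn <- neighborFrequency(coords, paste0("BC", 1:4), pT = 0.75)
    expect_identical(unname(fnn["BC5"]), 4L)
    expect_false("BC6" %in% names(fnn))
    expect_identical(neighborFrequency(coords, character(0), 0.5),
                     stats::setNames(integer(0), character(0)))
})

test_that("Pearson kurtosis uses population moments, non-excess", {
    expect_equal(pearsonKurtosis(c(-1, 1)), 1)
    expect_equal(pearsonKurtosis(c(-1, 1, -1, 1)), 1)
    set.seed(99)
    expect_equal(pearsonKurtosis(stats::rnorm(2e5)), 3, tolerance = 0.05)
    expect_error(pearsonKurtosis(rep(2, 5)), "degenerate")
})

test_that("the default pT grid spans 1-exDR/6 to 1-exDR in six steps", {
    expect_equal(defaultPTGrid(0.15),
                 c(0.975, 0.95, 0.925, 0.90, 0.875, 0.85))
    expect_equal(defaultPTGrid(0.3)[6], 0.7)
})

test_that("the sweep is deterministic and its chosen pair lies on the grid", {
    pool <- smallPool(seed = 17, nCells = 400, nDonors = 5)
    feats <- doubletFeatureMatrix(poolAssignmentTable(pool))
    s1 <- parameterSweep(feats, exDR = 0.15, nCDGrid = c(20L, 40L, 60L, 80L))
    s2 <- parameterSweep(feats, exDR = 0.15, nCDGrid = c(20L, 40L, 60L, 80L))
    expect_identical(s1, s2)
    expect_true(s1@chosenNCD %in% c(20L, 40L, 60L, 80L))
    expect_true(s1@chosenPT %in% defaultPTGrid(0.15))
    expect_true(s1@selectionPath %in% c("inflection", "max_K"))
    expect_identical(nrow(s1@grid), 24L)
    # every fNN table only holds counts between 1 and the confident set size
    for (key in names(s1@fnnTables)) {
        fnn <- s1@fnnTables[[key]]
        if (length(fnn)) expect_true(all(fnn >= 1L))
    }
})

test_that("graph doublet calls override singlets but never unmake doublets", {
    pool <- smallPool(seed = 23, nCells = 300, nDonors = 5)
    tab <- poolAssignmentTable(pool)
    res <- suppressWarnings(demultiplexPool(tab, exDR = 0.15,
                                            nCDGrid = c(10L, 20L, 30L)))
    tabDf <- as.data.frame(resultTable(res))
    # doublet-monotone: every Step-1 doublet is still a doublet at the end
    s1dbl <- tabDf$step1_label == "doublet"
    expect_true(all(tabDf$final_label[s1dbl] == "doublet"))
    # step2 flags only ever point at doublet final labels
    expect_true(all(tabDf$final_label[tabDf$step2_doublet] == "doublet"))
})

test_that("applyGraphDoublets example cases", {
    pool <- smallPool(seed = 29, nCells = 300, nDonors = 5)
    feats <- doubletFeatureMatrix(poolAssignmentTable(pool))
    sweep <- parameterSweep(feats, exDR = 0.15, nCDGrid = c(10L, 20L, 30L))
    labels <- stats::setNames(rep("donorA", nrow(feats)), rownames(feats))
    key <- sprintf("nCD%d_pT%s", sweep@chosenNCD, sprintf("%.6g", sweep@chosenPT))
    nPut <- length(sweep@fnnTables[[key]])
    out <- applyGraphDoublets(labels, sweep)
    expect_identical(sum(out$labels == "doublet"), nPut)
    expect_identical(out$nOverridden, nPut)
    # idempotent on an already-doublet labelling: zero overrides
    allDbl <- stats::setNames(rep("doublet", nrow(feats)), rownames(feats))
    out2 <- applyGraphDoublets(allDbl, sweep)
    expect_identical(out2$nOverridden, 0L)
    expect_identical(sum(out2$labels == "doublet"), nrow(feats))
})
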