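## Step 2: graph-based doublet detection.
##
## Seven doublet-related features from the constituent tools are percentile
## ranked (oriented so that higher rank = more doublet-like), a confident
## doublet seed set is found by walking a joint percentile threshold down
## from 99.99, all cells are embedded in the first two principal components
## of the z-scored features, and each cell's nearest-neighbour frequency
## (fNN) across the confident doublets is computed. The (nCD, pT) pair is
## selected by maximising the Pearson kurtosis of the fNN distribution over
## a parameter sweep.

## Orientation of each feature: +1 when larger values are more doublet-like.
.FEATURE_ORIENTATION <- c(
    demuxalot_doublet_prob = +1,
    demuxlet_llk_diff = -1,   # singlet - doublet log likelihood
    demuxlet_n_snps = +1,
    demuxlet_n_reads = +1,
    freemuxlet_llk_diff = -1,
    freemuxlet_n_snps = +1,
    freemuxlet_n_reads = +1,
    souporcell_log_prob_doublet = +1,
    vireo_prob_doublet = +1,
    vireo_doublet_logLikRatio = +1
)

#' Assemble the doublet feature matrix
#'
#' Collects the doublet-related feature columns of every tool in the table
#' into one numeric matrix (rows = barcodes, columns named
#' `<tool>_<feature>`), with an `orientation` attribute giving each column's
#' sign (+1 when larger values are more doublet-like). A feature column a
#' tool's file lacked is simply absent; per-cell missing values (cells a tool
#' did not cover under the union barcode policy) are imputed at the feature's
#' median, with a message. At least three feature columns must remain.
#'
#' @param table a [CellAssignmentTable].
#' @return numeric matrix with attribute `orientation`.
#' @export
doubletFeatureMatrix <- function(table) {
    cols <- list()
    for (id in toolIds(table)) {
        f <- getTool(table, id)@features
        for (fn in colnames(f))
            cols[[paste(id, fn, sep = "_")]] <- f[[fn]]
    }
    cols <- cols[names(cols) %in% names(.FEATURE_ORIENTATION)]
    if (length(cols) < 3L)
        stop(sprintf("need >=3 doublet features for graph-based detection; found %d",
                     length(cols)))
    m <- do.call(cbind, cols)
    rownames(m) <- barcodes(table)
    nImputed <- 0L
    for (j in seq_len(ncol(m))) {
        na <- is.na(m[, j])
        if (any(na)) {
            m[na, j] <- stats::median(m[, j], na.rm = TRUE)
            nImputed <- nImputed + sum(na)
        }
    }
    if (nImputed)
        message(sprintf("imputed %d missing feature value(s) at the column median", nImputed))
    attr(m, "orientation") <- .FEATURE_ORIENTATION[colnames(m)]
    m
}

#' Doublet-likelihood percentile ranks
#'
#' Orients a feature vector (multiplies by `orientation`) and assigns each
#' cell the percentile rank `100 * rank / n` with average ranks for ties, so
#' the most doublet-like cell has the highest percentile (at most 100). A
#' constant vector carries no information (every cell gets the tie-averaged
#' midpoint rank) and triggers a warning.
#'
#' @param values numeric vector (length >= 2, finite).
#' @param orientation `+1` or `-1`.
#' @return numeric vector of percentiles in `(0, 100]`.
#' @export
percentileRank <- function(values, orientation = 1) {
    stopifnot(length(values) >= 2L, all(is.finite(values)),
              orientation %in% c(-1, 1))
    if (max(values) == min(values))
        warning("all feature values identical; ranks carry no information")
    100 * rank(orientation * values, ties.method = "average") / length(values)
}

.oriented_ranks <- function(features) {
    orient <- attr(features, "orientation")
    r <- vapply(seq_len(ncol(features)),
                function(j) percentileRank(features[, j], orient[[j]]),
                numeric(nrow(features)))
    dimnames(r) <- dimnames(features)
    r
}

#' Identify confident doublets
#'
#' Starting from a joint percentile threshold of 99.99 and decreasing it by
#' 0.01 per iteration, finds the first threshold at which at least `nCD`
#' cells exceed the threshold in every feature simultaneously, and returns
#' all qualifying cells at that threshold (possibly more than `nCD`),
#' ordered from most to least doublet-like. If fewer than `nCD` cells ever
#' qualify (only possible when `nCD > n`), all cells are returned with a
#' warning.
#'
#' @param ranks matrix of oriented percentile ranks (cells x features).
#' @param nCD target number of confident doublets (>= 1).
#' @return character vector of barcodes, with attribute `threshold` (the
#'   stopping percentile).
#' @export
findConfidentDoublets <- function(ranks, nCD) {
    stopifnot(is.matrix(ranks), nCD >= 1)
    minRank <- apply(ranks, 1L, min)
    n <- length(minRank)
    ord <- order(-minRank, rownames(ranks), method = "radix")
    if (nCD > n) {
        warning(sprintf("nCD = %d exceeds the pool size %d; returning all cells", nCD, n))
        out <- rownames(ranks)[ord]
        attr(out, "threshold") <- 0
        return(out)
    }
    ## a cell qualifies at threshold t iff its minimum rank exceeds t, so the
    ## stopping threshold is the largest grid value (99.99, 99.98, ...) that
    ## is strictly below the nCD-th largest minimum rank
    mk <- minRank[ord[nCD]]
    k <- floor(round(mk * 100, 8))
    if (k / 100 >= mk) k <- k - 1L
    k <- min(k, 9999L)
    if (k < 0L) k <- 0L
    t <- k / 100
    qual <- minRank > t
    out <- rownames(ranks)[ord][seq_len(sum(qual))]
    attr(out, "threshold") <- t
    out
}

#' Embed the doublet features in two principal components
#'
#' Z-scores each feature column (dropping zero-variance columns with a
#' warning), then projects the cells onto the first two principal components
#' via a deterministic eigendecomposition of the covariance matrix. Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param features numeric matrix (cells x features), >= 2 informative
#'   columns and >= 3 cells.
#' @return numeric matrix (cells x 2) of PC scores, with attribute
#'   `varExplained`.
#' @export
pcaEmbed <- function(features) {
    stopifnot(is.matrix(features), nrow(features) >= 3L)
    sds <- apply(features, 2L, stats::sd)
    if (any(sds == 0)) {
        warning(sprintf("dropping zero-variance feature(s): %s",
                        paste(colnames(features)[sds == 0], collapse = ", ")))
        features <- features[, sds > 0, drop = FALSE]
        sds <- sds[sds > 0]
    }
    if (ncol(features) < 2L)
        stop("need >=2 informative features for the PCA embedding")
    z <- scale(features, center = TRUE, scale = TRUE)
    cv <- stats::cov(z)
    eg <- eigen(cv, symmetric = TRUE)
    v <- eg$vectors[, 1:2, drop = FALSE]
    for (j in 1:2) {
        lead <- which.max(abs(v[, j]))
        if (v[lead, j] < 0) v[, j] <- -v[, j]
    }
    scores <- z %*% v
    dimnames(scores) <- list(rownames(features), c("PC1", "PC2"))
    attr(scores, "varExplained") <- eg$values[1:2] / sum(pmax(eg$values, 0))
    scores
}

#' Nearest-neighbour frequencies around the confident doublets
#'
#' For each confident doublet, percentile-ranks all other cells by proximity
#' in the 2-PC embedding (closer cells get higher ranks) and marks the cells
#' whose proximity rank exceeds `100 * pT` as that doublet's nearest
#' neighbours. A cell's fNN is the number of confident doublets for which it
#' is a nearest neighbour; only cells with `fNN >= 1` (the putative
#' doublets) are returned.
#'
#' @param coords matrix of 2-PC scores with barcode rownames.
#' @param confident character vector of confident-doublet barcodes.
#' @param pT proximity percentile threshold in (0, 1).
#' @return named integer vector of fNN counts (possibly empty).
#' @export
neighborFrequency <- function(coords, confident, pT) {
    stopifnot(pT > 0, pT < 1, all(confident %in% rownames(coords)))
    if (!length(confident))
        return(stats::setNames(integer(0), character(0)))
    prox <- .proximity_ranks(coords, confident)
    fnn <- colSums(prox > 100 * pT, na.rm = TRUE)
    fnn <- fnn[fnn >= 1]
    storage.mode(fnn) <- "integer"
    fnn[order(names(fnn), method = "radix")]
}

## Percentile proximity ranks: one row per confident doublet, one column per
## cell; entry = percentile rank of the cell's proximity to that doublet
## (computed over the n-1 other cells, self = NA).
.proximity_ranks <- function(coords, confident) {
    n <- nrow(coords)
    ci <- match(confident, rownames(coords))
    d2 <- outer(coords[ci, 1L], coords[, 1L], "-")^2 +
        outer(coords[ci, 2L], coords[, 2L], "-")^2
    prox <- matrix(NA_real_, nrow = length(ci), ncol = n,
                   dimnames = list(confident, rownames(coords)))
    for (i in seq_along(ci)) {
        others <- setdiff(seq_len(n), ci[i])
        ## closer => higher percentile
        prox[i, others] <- 100 * rank(-d2[i, others], ties.method = "average") /
            (n - 1L)
    }
    prox
}

#' Pearson's (non-excess) kurtosis
#'
#' Computes `mean(((x - mu) / sigma)^4)` with population mean and standard
#' deviation; a normal distribution gives 3. A constant vector (zero
#' standard deviation) is an error.
#'
#' @param values numeric vector of length >= 2.
#' @return the kurtosis.
#' @export
pearsonKurtosis <- function(values) {
    stopifnot(length(values) >= 2L)
    mu <- mean(values)
    sig <- sqrt(mean((values - mu)^2))
    if (sig == 0)
        stop("degenerate distribution: zero standard deviation")
    mean(((values - mu) / sig)^4)
}

#' Default proximity-threshold grid
#'
#' Six evenly spaced pT values `1 - k * exDR / 6` for `k = 1..6`, spanning
#' `1 - exDR/6` down to `1 - exDR`.
#'
#' @param exDR expected doublet rate in (0, 1).
#' @return numeric vector of six pT values.
#' @export
defaultPTGrid <- function(exDR) {
    stopifnot(exDR > 0, exDR < 1)
    1 - (1:6) * exDR / 6
}

#' Kurtosis-driven (nCD, pT) parameter sweep
#'
#' Runs the full graph-based doublet detection at every combination of the
#' confident-doublet count grid and the proximity-threshold grid: finds the
#' confident doublets, computes the fNN table, and scores the grid point by
#' the Pearson kurtosis K of its fNN distribution (grid points whose fNN
#' distribution is degenerate are given `K = -Inf` and skipped). The pT with
#' the highest mean K across the nCD grid is selected first; along that pT
#' slice, nCD is taken at the first inflection of K versus nCD (sign change
#' of the discrete second difference) when one exists, otherwise at the
#' maximum K. Ties resolve toward smaller nCD and larger pT (fewer doublet
#' calls).
#'
#' @param features matrix from [doubletFeatureMatrix()].
#' @param exDR expected doublet rate in (0, 1).
#' @param nCDGrid integer grid of confident-doublet counts (default 50-300
#'   by 50).
#' @param pTGrid numeric grid of proximity thresholds (default
#'   [defaultPTGrid()]).
#' @return a [SweepResult].
#' @export
parameterSweep <- function(features, exDR, nCDGrid = seq(50L, 300L, 50L),
                           pTGrid = NULL) {
    stopifnot(exDR > 0, exDR < 1, length(nCDGrid) > 0)
    if (is.null(pTGrid)) pTGrid <- defaultPTGrid(exDR)
    nCDGrid <- sort(unique(as.integer(nCDGrid)))
    pTGrid <- sort(unique(pTGrid), decreasing = TRUE)
    ranks <- .oriented_ranks(features)
    coords <- pcaEmbed(features)
    confidentSets <- lapply(nCDGrid, function(ncd)
        suppressWarnings(findConfidentDoublets(ranks, ncd)))
    names(confidentSets) <- as.character(nCDGrid)
    ## confident sets are nested in nCD, so proximity ranks are computed once
    ## for the largest set and reused
    unionSet <- confidentSets[[length(confidentSets)]]
    prox <- .proximity_ranks(coords, unionSet)
    grid <- expand.grid(nCD = nCDGrid, pT = pTGrid, KEEP.OUT.ATTRS = FALSE)
    grid$K <- NA_real_
    grid$nPutative <- NA_integer_
    fnnTables <- vector("list", nrow(grid))
    names(fnnTables) <- sprintf("nCD%d_pT%s", grid$nCD, sprintf("%.6g", grid$pT))
    for (g in seq_len(nrow(grid))) {
        conf <- confidentSets[[as.character(grid$nCD[g])]]
        sub <- prox[match(conf, unionSet), , drop = FALSE]
        fnn <- colSums(sub > 100 * grid$pT[g], na.rm = TRUE)
        fnn <- fnn[fnn >= 1]
        storage.mode(fnn) <- "integer"
        fnn <- fnn[order(names(fnn), method = "radix")]
        fnnTables[[g]] <- fnn
        grid$nPutative[g] <- length(fnn)
        grid$K[g] <- if (length(fnn) >= 2L &&
                         stats::sd(fnn) > 0)
            pearsonKurtosis(as.numeric(fnn)) else -Inf
    }
    if (all(!is.finite(grid$K)))
        stop("all sweep grid points are degenerate; set (nCD, pT) manually")
    ## Select pT by the highest mean K over the nCD grid (degenerate points
    ## excluded from the mean); ties resolve to the larger pT because the
    ## grid is ordered decreasing and which.max takes the first maximum.
    meanK <- vapply(pTGrid, function(p) {
        k <- grid$K[grid$pT == p & is.finite(grid$K)]
        if (length(k)) mean(k) else -Inf
    }, numeric(1))
    chosenPT <- pTGrid[which.max(meanK)]
    slice <- grid[grid$pT == chosenPT, ]
    slice <- slice[order(slice$nCD), ]
    kk <- slice$K
    chosenNCD <- NA_integer_
    path <- "max_K"
    if (all(is.finite(kk)) && length(kk) >= 4L) {
        d2 <- diff(kk, differences = 2L)
        ## an inflection is identifiable only when the curvature sign change
        ## would be visible on the plotted K curve: empirical kurtosis
        ## estimates wiggle, so second differences fluctuate around zero in
        ## flat stretches. A sign change counts only if the curvature on
        ## both sides amounts to at least 5% of the slice's total K range.
        tol <- 0.05 * diff(range(kk))
        flip <- which(d2[-length(d2)] * d2[-1L] < 0 &
                      pmin(abs(d2[-length(d2)]), abs(d2[-1L])) >= tol)
        if (length(flip)) {
            ## curvature changes sign between the interior points
            ## nCD[flip+1] and nCD[flip+2]; take the smaller
            chosenNCD <- slice$nCD[flip[1L] + 1L]
            path <- "inflection"
        }
    }
    if (is.na(chosenNCD))
        chosenNCD <- slice$nCD[which.max(kk)]
    new("SweepResult", exDR = exDR, grid = grid, fnnTables = fnnTables,
        chosenNCD = as.integer(chosenNCD), chosenPT = chosenPT,
        selectionPath = path)
}

#' Apply the graph-based doublet calls
#'
#' Overrides the Step-1 label of every putative doublet at the sweep's chosen
#' grid point (every cell with `fNN >= 1` there) with a doublet label; all
#' other labels are unchanged.
#'
#' @param labels named character vector of per-cell labels (donor id,
#'   `"doublet"` or `"unassigned"`).
#' @param sweep a [SweepResult].
#' @return list with `labels` (updated vector) and `nOverridden` (number of
#'   former singlet labels converted).
#' @export
applyGraphDoublets <- function(labels, sweep) {
    stopifnot(is(sweep, "SweepResult"))
    key <- sprintf("nCD%d_pT%s", sweep@chosenNCD, sprintf("%.6g", sweep@chosenPT))
    fnn <- sweep@fnnTables[[key]]
    hit <- names(fnn)[names(fnn) %in% names(labels)]
    was <- labels[hit]
    labels[hit] <- .DBL
    list(labels = labels,
         nOverridden = sum(was != .DBL & was != .UNS))
}
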