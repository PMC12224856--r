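## Synthetic pools: ground-truth-labelled cells plus matching constituent
## tool outputs with the assignment-level statistical structure the ensemble
## assumes (configurable per-tool accuracies, probability calibration, and
## doublet-shifted feature distributions). Everything is deterministic given
## the seed, so every pipeline stage is testable without external data.

#' Default per-tool error profiles
#'
#' Singlet accuracy, doublet sensitivity, doublet specificity and unassigned
#' rate for each constituent tool, plus the Beta shape parameters of the
#' assignment-probability calibration: correct calls draw probabilities from
#' `Beta(20, 1)` and wrong calls from `Beta(2, 2)`, so probability is
#' informative of correctness.
#'
#' @return named list of per-tool profile lists.
#' @export
defaultToolProfiles <- function() {
    prof <- function(acc, sens, spec)
        list(singletAccuracy = acc, doubletSensitivity = sens,
             doubletSpecificity = spec, unassignedRate = 0.02,
             probCalibration = c(alphaCorrect = 20, betaCorrect = 1,
                                 alphaWrong = 2, betaWrong = 2))
    out <- list(demuxalot = prof(0.95, 0.55, 0.99),
                demuxlet = prof(0.94, 0.60, 0.97),
                souporcell = prof(0.90, 0.55, 0.96),
                vireo = prof(0.93, 0.50, 0.99))
    ## demuxalot's posterior table cannot express an unassigned cell (the
    ## argmax class always exists), so its unassigned rate is zero
    out$demuxalot$unassignedRate <- 0
    out
}

#' Default doublet feature model
#'
#' Singlet mean, doublet mean and common standard deviation of the seven
#' doublet-related features. Every doublet mean sits two standard deviations
#' from the singlet mean in the doublet-like direction of that feature's
#' orientation.
#'
#' @return named list of `c(meanSinglet, meanDoublet, sd)` triples keyed by
#'   `<tool>_<feature>`.
#' @export
defaultFeatureModel <- function() {
    list(
        demuxalot_doublet_prob = c(meanSinglet = 0.05, meanDoublet = 0.25, sd = 0.10),
        demuxlet_llk_diff = c(meanSinglet = 8, meanDoublet = 2, sd = 3),
        demuxlet_n_snps = c(meanSinglet = 120, meanDoublet = 200, sd = 40),
        demuxlet_n_reads = c(meanSinglet = 2000, meanDoublet = 3200, sd = 600),
        souporcell_log_prob_doublet = c(meanSinglet = -40, meanDoublet = -16, sd = 12),
        vireo_prob_doublet = c(meanSinglet = 0.05, meanDoublet = 0.25, sd = 0.10),
        vireo_doublet_logLikRatio = c(meanSinglet = -3, meanDoublet = 0, sd = 1.5)
    )
}

#' Specify a synthetic pool
#'
#' Validates and assembles the parameters of a synthetic pool: the pool
#' size, number of donors, heterogenic doublet rate, donor proportions,
#' per-tool error profiles, the doublet feature model, an optional
#' error-correlation knob (probability that a cell is "hard", forcing an
#' error in every tool), and the seed.
#'
#' @param nCells number of cells (>= 10).
#' @param nDonors number of pooled donors (>= 2).
#' @param doubletRate heterogenic doublet rate in (0, 1); default 0.15.
#' @param donorProportions optional simplex vector of length `nDonors`
#'   (default uniform).
#' @param toolProfiles named list as [defaultToolProfiles()].
#' @param featureModel named list as [defaultFeatureModel()].
#' @param errorCorrelation probability of a shared "hard cell" on which all
#'   tools err (default 0: independent tool errors).
#' @param seed integer seed.
#' @return a `SyntheticPoolSpec` (validated list).
#' @export
syntheticPoolSpec <- function(nCells, nDonors, doubletRate = 0.15,
                              donorProportions = NULL,
                              toolProfiles = defaultToolProfiles(),
                              featureModel = defaultFeatureModel(),
                              errorCorrelation = 0, seed = 1L) {
    if (nDonors < 2L) stop("need at least 2 donors")
    if (doubletRate <= 0 || doubletRate >= 1)
        stop("doubletRate must lie strictly in (0, 1)")
    if (is.null(donorProportions))
        donorProportions <- rep(1 / nDonors, nDonors)
    if (length(donorProportions) != nDonors ||
        abs(sum(donorProportions) - 1) > 1e-9 || any(donorProportions <= 0))
        stop("donorProportions must be a positive simplex vector of length nDonors")
    for (p in toolProfiles) {
        rates <- c(p$singletAccuracy, p$doubletSensitivity,
                   p$doubletSpecificity, p$unassignedRate)
        if (any(rates < 0 | rates > 1))
            stop("tool profile rates must lie in [0, 1]")
    }
    structure(list(nCells = as.integer(nCells), nDonors = as.integer(nDonors),
                   doubletRate = doubletRate,
                   donorProportions = donorProportions,
                   toolProfiles = toolProfiles, featureModel = featureModel,
                   errorCorrelation = errorCorrelation,
                   seed = as.integer(seed)),
              class = "SyntheticPoolSpec")
}

.donor_names <- function(S) sprintf("donor%02d", seq_len(S))

## Draw per-call assignment probabilities from the calibration components.
.draw_probs <- function(correct, calib) {
    n <- length(correct)
    p <- numeric(n)
    nC <- sum(correct)
    p[correct] <- stats::rbeta(nC, calib[["alphaCorrect"]], calib[["betaCorrect"]])
    p[!correct] <- stats::rbeta(n - nC, calib[["alphaWrong"]], calib[["betaWrong"]])
    p
}

#' Simulate a synthetic pool with matching tool outputs
#'
#' Draws ground-truth labels (each cell a heterogenic doublet with the
#' spec'd rate, donors by the donor proportions; a doublet is an unordered
#' pair of distinct donors) and then, for each tool: a true singlet is first
#' called doublet with probability `1 - doubletSpecificity`, otherwise its
#' donor with probability `singletAccuracy` and a random wrong donor
#' otherwise; a true doublet is called doublet with probability
#' `doubletSensitivity` and a random donor otherwise; finally calls are
#' replaced by unassigned at the unassigned rate. Assignment probabilities
#' come from the correct/wrong Beta calibration components, and the seven
#' doublet features from their singlet/doublet normal components. Demuxalot
#' receives a full class-posterior table consistent with its call and
#' doublet mass; Souporcell receives cluster posteriors. The result is fully
#' deterministic given the spec's seed.
#'
#' @param spec a [syntheticPoolSpec()].
#' @return list of class `SyntheticPool` with elements `truth` (named label
#'   vector), `truthPairs` (the two source donors of each doublet),
#'   `toolOutputs` (list of [ToolOutput]), `spec`, `seed`.
#' @export
simulatePool <- function(spec) {
    stopifnot(inherits(spec, "SyntheticPoolSpec"))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    n <- spec$nCells
    S <- spec$nDonors
    donors <- .donor_names(S)
    barcode <- sprintf("BC%06d-1", seq_len(n))
    isDbl <- stats::runif(n) < spec$doubletRate
    donor <- sample(donors, n, replace = TRUE, prob = spec$donorProportions)
    pair2 <- vapply(which(isDbl), function(i)
        sample(setdiff(donors, donor[i]), 1L), character(1))
    truth <- ifelse(isDbl, .DBL, donor)
    names(truth) <- barcode
    truthPairs <- data.frame(barcode = barcode[isDbl],
                             donorA = donor[isDbl], donorB = pair2,
                             stringsAsFactors = FALSE)
    hard <- stats::runif(n) < spec$errorCorrelation
    feats <- lapply(spec$featureModel, function(fm)
        stats::rnorm(n, ifelse(isDbl, fm[["meanDoublet"]], fm[["meanSinglet"]]),
                     fm[["sd"]]))
    ## demuxlet SNP/read counts are integers in real files
    for (fn in c("demuxlet_n_snps", "demuxlet_n_reads"))
        if (fn %in% names(feats)) feats[[fn]] <- round(pmax(feats[[fn]], 1))
    outs <- list()
    for (id in names(spec$toolProfiles)) {
        pr <- spec$toolProfiles[[id]]
        call <- character(n)
        tdonor <- rep(NA_character_, n)
        ## singlets: doublet false positives override first, then accuracy
        sngErr <- (stats::runif(n) >= pr$singletAccuracy) | hard
        dblFP <- stats::runif(n) < (1 - pr$doubletSpecificity)
        wrong <- rep(NA_character_, n)
        need <- which(!isDbl & sngErr & !dblFP)
        if (length(need) && S > 1L) {
            ## a wrong donor drawn uniformly from the S-1 others
            shift <- sample.int(S - 1L, length(need), replace = TRUE)
            wrong[need] <- donors[((match(donor[need], donors) - 1L + shift) %% S) + 1L]
        }
        sng <- !isDbl
        call[sng & dblFP] <- .DBL
        ok <- sng & !dblFP & !sngErr
        call[ok] <- "singlet"; tdonor[ok] <- donor[ok]
        bad <- sng & !dblFP & sngErr
        call[bad] <- "singlet"; tdonor[bad] <- wrong[bad]
        ## doublets: detected with the tool's sensitivity, else a random donor
        dblHit <- (stats::runif(n) < pr$doubletSensitivity) & !hard
        call[isDbl & dblHit] <- .DBL
        missIdx <- which(isDbl & !dblHit)
        call[missIdx] <- "singlet"
        tdonor[missIdx] <- sample(donors, length(missIdx), replace = TRUE)
        uns <- stats::runif(n) < pr$unassignedRate
        call[uns] <- .UNS
        tdonor[uns] <- NA_character_
        correct <- (call == "singlet" & !is.na(tdonor) & tdonor == truth) |
            (call == .DBL & isDbl)
        prob <- .draw_probs(correct, pr$probCalibration)
        prob[call == .UNS] <- NA_real_
        outs[[id]] <- .build_tool_output(id, barcode, call, tdonor, prob,
                                         feats, donors, isDbl, truthPairs)
    }
    structure(list(truth = truth, truthPairs = truthPairs, toolOutputs = outs,
                   spec = spec, seed = spec$seed),
              class = "SyntheticPool")
}

## Assemble one tool's ToolOutput, including the tool-specific feature
## columns and (for demuxalot/souporcell) full class posteriors consistent
## with what the native-file emitters will write.
.build_tool_output <- function(id, barcode, call, tdonor, prob, feats,
                               donors, isDbl, truthPairs) {
    n <- length(barcode)
    S <- length(donors)
    pick <- function(fn) feats[[fn]]
    if (id %in% c("demuxlet", "freemuxlet")) {
        features <- data.frame(llk_diff = pick("demuxlet_llk_diff"),
                               n_snps = pick("demuxlet_n_snps"),
                               n_reads = pick("demuxlet_n_reads"))
        return(new("ToolOutput", toolId = id, barcode = barcode, call = call,
                   donor = tdonor, prob = prob, features = features))
    }
    if (id == "vireo") {
        features <- data.frame(
            prob_doublet = pmin(pmax(pick("vireo_prob_doublet"), 0.001), 0.999),
            doublet_logLikRatio = pick("vireo_doublet_logLikRatio"))
        return(new("ToolOutput", toolId = id, barcode = barcode, call = call,
                   donor = tdonor, prob = prob, features = features))
    }
    if (id == "souporcell") {
        ## cluster posteriors: assigned cluster gets the drawn probability,
        ## the rest is spread uniformly; doublet/unassigned rows uniform
        cp <- matrix(1 / S, nrow = n, ncol = S, dimnames = list(barcode, donors))
        sng <- call == "singlet"
        p <- pmin(pmax(prob, 1 / S + 1e-6), 0.999)
        if (any(sng)) {
            cp[sng, ] <- (1 - p[sng]) / (S - 1)
            cp[cbind(which(sng), match(tdonor[sng], donors))] <- p[sng]
        }
        ## the clusters.tsv dialect carries no posterior for non-singlet
        ## rows, so none is claimed in memory either
        prob2 <- rep(NA_real_, n)
        prob2[sng] <- p[sng]
        features <- data.frame(log_prob_doublet = pick("souporcell_log_prob_doublet"))
        return(new("ToolOutput", toolId = id, barcode = barcode, call = call,
                   donor = tdonor, prob = prob2, features = features,
                   classProbs = cp))
    }
    ## demuxalot: posterior over donors + one aggregated doublet mass; the
    ## doublet mass of singlet-called cells follows the feature model,
    ## clamped into the simplex below the assigned donor's mass
    d <- pmin(pmax(pick("demuxalot_doublet_prob"), 0.001), 0.999)
    ## the assigned class must stay the row argmax after the remaining mass
    ## is spread, which q > 1/S guarantees
    q <- pmin(pmax(prob, 1 / S + 0.005), 0.998)
    cp <- matrix(0, nrow = n, ncol = S + 1L,
                 dimnames = list(barcode, c(donors, .DBL)))
    sng <- call == "singlet"
    dbl <- call == .DBL
    uns <- call == .UNS
    dS <- pmin(d[sng], (1 - q[sng]) * 0.9, q[sng] * 0.9)
    cp[sng, ] <- (1 - q[sng] - dS) / (S - 1)
    cp[cbind(which(sng), match(tdonor[sng], donors))] <- q[sng]
    cp[sng, .DBL] <- dS
    if (any(dbl)) {
        cp[dbl, ] <- (1 - q[dbl]) / S
        cp[dbl, .DBL] <- q[dbl]
    }
    if (any(uns)) cp[uns, ] <- 1 / (S + 1L)
    dFeat <- cp[, .DBL]
    prob2 <- unname(apply(cp[, donors, drop = FALSE], 1L, max))
    new("ToolOutput", toolId = "demuxalot", barcode = barcode, call = call,
        donor = tdonor, prob = prob2,
        features = data.frame(doublet_prob = unname(dFeat)), classProbs = cp)
}

#' Write a synthetic pool as native-format tool files
#'
#' Emits the pool's tool outputs in the constituent tools' native dialects —
#' a Demuxlet/Freemuxlet `.best`, a Souporcell `clusters.tsv`, a Vireo
#' `donor_ids.tsv` and a Demuxalot probability table — plus a `truth.tsv`
#' (barcode, label). The files round-trip through the package's readers:
#' labels exactly, numeric values to 1e-9.
#'
#' @param pool a `SyntheticPool` from [simulatePool()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths.
#' @export
emitToolFiles <- function(pool, dir) {
    stopifnot(inherits(pool, "SyntheticPool"))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop(sprintf("cannot create directory: %s", dir))
    fmt <- function(x) sprintf("%.12g", x)
    paths <- character()
    for (id in names(pool$toolOutputs)) {
        t <- pool$toolOutputs[[id]]
        if (id %in% c("demuxlet", "freemuxlet")) {
            p <- file.path(dir, paste0(id, ".best"))
            typ <- c(singlet = "SNG", doublet = "DBL", unassigned = "AMB")[t@call]
            df <- data.frame(BARCODE = t@barcode, DROPLET.TYPE = unname(typ),
                             SNG.BEST.GUESS = ifelse(is.na(t@donor), ".", t@donor),
                             SNG.POSTERIOR = fmt(t@prob),
                             DIFF.LLK.SNG.DBL = fmt(t@features$llk_diff),
                             NUM.SNPS = fmt(t@features$n_snps),
                             NUM.READS = fmt(t@features$n_reads))
        } else if (id == "vireo") {
            p <- file.path(dir, "donor_ids.tsv")
            did <- ifelse(t@call == "singlet", t@donor, t@call)
            df <- data.frame(cell = t@barcode, donor_id = did,
                             prob_max = fmt(t@prob),
                             prob_doublet = fmt(t@features$prob_doublet),
                             n_vars = "0", best_singlet = ifelse(is.na(t@donor), ".", t@donor),
                             best_doublet = ".",
                             doublet_logLikRatio = fmt(t@features$doublet_logLikRatio))
        } else if (id == "souporcell") {
            p <- file.path(dir, "clusters.tsv")
            status <- ifelse(t@call == "singlet", "singlet",
                             ifelse(t@call == .DBL, "doublet", .UNS))
            cls <- colnames(t@classProbs)
            assignment <- ifelse(t@call == "singlet", t@donor,
                                 ifelse(t@call == .DBL,
                                        paste(cls[1L], cls[2L], sep = "/"), "."))
            lp <- log(t@classProbs)
            df <- data.frame(barcode = t@barcode, status = status,
                             assignment = assignment,
                             log_prob_singleton = fmt(log(apply(t@classProbs, 1L, max))),
                             log_prob_doublet = fmt(t@features$log_prob_doublet),
                             check.names = FALSE)
            for (j in seq_along(cls))
                df[[paste0("cluster", cls[j])]] <- fmt(lp[, j])
        } else { # demuxalot
            p <- file.path(dir, "demuxalot_probs.tsv")
            donors <- setdiff(colnames(t@classProbs), .DBL)
            ## the aggregated doublet mass is emitted as one synthetic pair
            ## class so the "+" convention round-trips
            pairName <- paste(donors[1L], donors[2L], sep = "+")
            df <- data.frame(BARCODE = t@barcode, check.names = FALSE)
            for (dn in donors) df[[dn]] <- fmt(t@classProbs[, dn])
            df[[pairName]] <- fmt(t@classProbs[, .DBL])
        }
        utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[[id]] <- p
    }
    tp <- file.path(dir, "truth.tsv")
    utils::write.table(data.frame(barcode = names(pool$truth),
                                  label = unname(pool$truth)),
                       tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[["truth"]] <- tp
    paths
}

#' Benchmark preset scenarios
#'
#' Named synthetic-pool presets mirroring common benchmark axes: a
#' sample-size sweep over 4-80 pooled donors at a 15% doublet rate; a
#' cell-count sweep from 8,000 to 48,000 cells with the doublet rate scaling
#' at 6% per 8,000 pooled cells; and donor-underrepresentation presets with
#' one donor at 10-90% of the others' share at an 18% doublet rate.
#'
#' @param nCells pool size used for the sample-size and underrepresentation
#'   presets (default 10000).
#' @param seed base seed stored in every preset.
#' @return named list of `SyntheticPoolSpec` objects.
#' @export
presetScenarios <- function(nCells = 10000L, seed = 1L) {
    presets <- list()
    for (S in c(4L, seq(8L, 80L, 8L)))
        presets[[sprintf("samples_%02d", S)]] <-
            syntheticPoolSpec(nCells, S, doubletRate = 0.15, seed = seed)
    for (nc in seq(8000L, 48000L, 8000L))
        presets[[sprintf("cells_%05d", nc)]] <-
            syntheticPoolSpec(nc, 24L, doubletRate = 0.06 * nc / 8000, seed = seed)
    for (f in c(0.10, 0.30, 0.50, 0.70, 0.90)) {
        S <- 24L
        w <- c(f, rep(1, S - 1L))
        presets[[sprintf("underrep_%02d", round(100 * f))]] <-
            syntheticPoolSpec(nCells, S, doubletRate = 0.18,
                              donorProportions = w / sum(w), seed = seed)
    }
    presets
}
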