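## Parsers for the native output files of the constituent demultiplexers.
## Each reader returns a ToolOutput in the tool-neutral schema; all format
## problems raise errors that name the offending column or line.

.read_tsv <- function(path, sep = "\t") {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "", colClasses = "character")
}

.require_columns <- function(df, cols, path) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(sprintf("%s: missing mandatory column(s): %s",
                     basename(path), paste(miss, collapse = ", ")))
}

.check_unique_barcodes <- function(bc, path) {
    if (anyDuplicated(bc))
        stop(sprintf("%s: duplicate barcode(s): %s", basename(path),
                     paste(unique(bc[duplicated(bc)])[1:min(3, sum(duplicated(bc)))],
                           collapse = ", ")))
}

## Numeric coercion that reports the 1-based data line of the first failure.
.as_numeric_checked <- function(x, column, path) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(x) & toupper(x) != "NA")
    if (length(bad))
        stop(sprintf("%s: unparseable numeric in column '%s' at data line %d ('%s')",
                     basename(path), column, bad[1], x[bad[1]]))
    out
}

#' Read a Demuxlet/Freemuxlet `.best` file
#'
#' Parses the tab-separated `.best` output of Demuxlet or Freemuxlet into a
#' [ToolOutput]. `SNG` droplets become singlets assigned to their best-guess
#' donor, `DBL` droplets doublets, `AMB` droplets unassigned. The singlet
#' posterior becomes the assignment probability, and three doublet-related
#' features are retained: the singlet-minus-doublet log-likelihood difference
#' (`llk_diff`), the number of SNPs (`n_snps`) and the number of reads
#' (`n_reads`) per cell.
#'
#' @param path path to the `.best` file.
#' @param toolId `"demuxlet"` (default) or `"freemuxlet"`.
#' @param columns named list overriding the default column names
#'   (`barcode`, `dropletType`, `bestGuess`, `posterior`, `llkDiff`,
#'   `nSnps`, `nReads`).
#' @return a [ToolOutput].
#' @export
readDemuxletBest <- function(path, toolId = c("demuxlet", "freemuxlet"),
                             columns = list()) {
    toolId <- match.arg(toolId)
    defaults <- list(barcode = "BARCODE", dropletType = "DROPLET.TYPE",
                     bestGuess = "SNG.BEST.GUESS", posterior = "SNG.POSTERIOR",
                     llkDiff = "DIFF.LLK.SNG.DBL", nSnps = "NUM.SNPS",
                     nReads = "NUM.READS")
    columns <- utils::modifyList(defaults, columns)
    df <- .read_tsv(path)
    .require_columns(df, unlist(columns), path)
    bc <- df[[columns$barcode]]
    .check_unique_barcodes(bc, path)
    typ <- toupper(df[[columns$dropletType]])
    if (!all(typ %in% c("SNG", "DBL", "AMB")))
        stop(sprintf("%s: droplet type must be SNG/DBL/AMB", basename(path)))
    call <- c(SNG = "singlet", DBL = .DBL, AMB = .UNS)[typ]
    donor <- ifelse(call == "singlet", df[[columns$bestGuess]], NA_character_)
    feats <- data.frame(
        llk_diff = .as_numeric_checked(df[[columns$llkDiff]], columns$llkDiff, path),
        n_snps = .as_numeric_checked(df[[columns$nSnps]], columns$nSnps, path),
        n_reads = .as_numeric_checked(df[[columns$nReads]], columns$nReads, path)
    )
    new("ToolOutput", toolId = toolId, barcode = bc, call = unname(call),
        donor = donor,
        prob = .as_numeric_checked(df[[columns$posterior]], columns$posterior, path),
        features = feats)
}

#' Read a Souporcell `clusters.tsv` file
#'
#' Parses Souporcell's `clusters.tsv` into a [ToolOutput]. Singlet rows are
#' assigned the cluster id in the `assignment` column (`"a/b"` assignments
#' are doublets regardless of status), and the doublet log-probability is
#' retained as a feature. When per-cluster log-probability columns (named
#' `cluster*`) are present, they are exponentiated and normalised into a
#' per-class posterior; the assignment probability of a singlet is the
#' posterior of its assigned cluster.
#'
#' @param path path to `clusters.tsv`.
#' @return a [ToolOutput] with `toolId = "souporcell"`.
#' @export
readSouporcellClusters <- function(path) {
    df <- .read_tsv(path)
    .require_columns(df, c("barcode", "status", "assignment",
                           "log_prob_singleton", "log_prob_doublet"), path)
    bc <- df$barcode
    .check_unique_barcodes(bc, path)
    status <- tolower(df$status)
    if (!all(status %in% c("singlet", "doublet", .UNS)))
        stop(sprintf("%s: status must be singlet/doublet/unassigned", basename(path)))
    call <- ifelse(status == "singlet", "singlet",
                   ifelse(status == "doublet", .DBL, .UNS))
    ## an "a/b" assignment denotes a doublet whatever the status column says
    call[grepl("/", df$assignment, fixed = TRUE)] <- .DBL
    donor <- ifelse(call == "singlet", df$assignment, NA_character_)
    feats <- data.frame(
        log_prob_doublet = .as_numeric_checked(df$log_prob_doublet,
                                               "log_prob_doublet", path)
    )
    clusterCols <- grep("^cluster", colnames(df), value = TRUE)
    prob <- rep(NA_real_, length(bc))
    classProbs <- NULL
    if (length(clusterCols)) {
        lp <- vapply(clusterCols,
                     function(cc) .as_numeric_checked(df[[cc]], cc, path),
                     numeric(length(bc)))
        lp <- matrix(lp, nrow = length(bc),
                     dimnames = list(bc, sub("^cluster[._]?", "", clusterCols)))
        ## softmax per row, guarded against -Inf-like values
        mx <- apply(lp, 1L, max)
        ex <- exp(lp - mx)
        classProbs <- ex / rowSums(ex)
        idx <- match(donor, colnames(classProbs))
        ok <- !is.na(idx)
        prob[ok] <- classProbs[cbind(which(ok), idx[ok])]
    } else {
        warning(sprintf("%s: no per-cluster columns; assignment probabilities missing",
                        basename(path)))
    }
    new("ToolOutput", toolId = "souporcell", barcode = bc, call = call,
        donor = donor, prob = prob, features = feats, classProbs = classProbs)
}

#' Read a Vireo `donor_ids.tsv` file
#'
#' Parses Vireo's `donor_ids.tsv` into a [ToolOutput]. The `donor_id` column
#' values `"doublet"` and `"unassigned"` map to the corresponding calls;
#' anything else is a singlet donor. `prob_max` becomes the assignment
#' probability; `prob_doublet` and `doublet_logLikRatio` are retained as
#' doublet-related features.
#'
#' @param path path to `donor_ids.tsv`.
#' @return a [ToolOutput] with `toolId = "vireo"`.
#' @export
readVireoDonorIds <- function(path) {
    df <- .read_tsv(path)
    .require_columns(df, c("cell", "donor_id", "prob_max", "prob_doublet",
                           "doublet_logLikRatio"), path)
    bc <- df$cell
    .check_unique_barcodes(bc, path)
    did <- df$donor_id
    call <- ifelse(did == .DBL, .DBL, ifelse(did == .UNS, .UNS, "singlet"))
    feats <- data.frame(
        prob_doublet = .as_numeric_checked(df$prob_doublet, "prob_doublet", path),
        doublet_logLikRatio = .as_numeric_checked(df$doublet_logLikRatio,
                                                  "doublet_logLikRatio", path)
    )
    new("ToolOutput", toolId = "vireo", barcode = bc, call = call,
        donor = ifelse(call == "singlet", did, NA_character_),
        prob = .as_numeric_checked(df$prob_max, "prob_max", path),
        features = feats)
}

#' Read a Demuxalot posterior-probability table
#'
#' Parses a Demuxalot probability table (comma- or tab-delimited; detected
#' from the header) whose first column holds barcodes and whose remaining
#' columns are per-class posterior probabilities. Doublet classes are named
#' by joining two donor ids with `"+"`. Each row must sum to 1 within 1e-3.
#' The label is the argmax class (a doublet when the argmax is a `"+"`
#' class); the `doublet_prob` feature is the summed mass of all `"+"`
#' classes; the assignment probability is the largest single-donor mass.
#' The stored class posteriors aggregate all `"+"` classes into one
#' `"doublet"` column.
#'
#' @param path path to the table.
#' @return a [ToolOutput] with `toolId = "demuxalot"`.
#' @export
readDemuxalotProbs <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    hdr <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(hdr, gregexpr(",", hdr, fixed = TRUE))) >
               lengths(regmatches(hdr, gregexpr("\t", hdr, fixed = TRUE)))) "," else "\t"
    df <- .read_tsv(path, sep = sep)
    if (ncol(df) < 3L)
        stop(sprintf("%s: expected a barcode column plus >=2 class columns",
                     basename(path)))
    bc <- df[[1L]]
    .check_unique_barcodes(bc, path)
    classCols <- colnames(df)[-1L]
    pm <- vapply(classCols, function(cc) .as_numeric_checked(df[[cc]], cc, path),
                 numeric(length(bc)))
    pm <- matrix(pm, nrow = length(bc), dimnames = list(bc, classCols))
    rs <- rowSums(pm)
    bad <- which(abs(rs - 1) > 1e-3)
    if (length(bad))
        stop(sprintf("%s: class probabilities at data line %d sum to %.4f (not 1 within 1e-3)",
                     basename(path), bad[1], rs[bad[1]]))
    isPair <- grepl("+", classCols, fixed = TRUE)
    if (!any(isPair))
        warning(sprintf("%s: no '+'-named doublet classes; doublet_prob set to 0",
                        basename(path)))
    dblProb <- if (any(isPair)) rowSums(pm[, isPair, drop = FALSE]) else
        rep(0, length(bc))
    donorMat <- pm[, !isPair, drop = FALSE]
    argmax <- classCols[max.col(pm, ties.method = "first")]
    call <- ifelse(grepl("+", argmax, fixed = TRUE), .DBL, "singlet")
    donor <- ifelse(call == "singlet", argmax, NA_character_)
    classProbs <- cbind(donorMat, doublet = dblProb)
    new("ToolOutput", toolId = "demuxalot", barcode = bc, call = call,
        donor = donor, prob = unname(apply(donorMat, 1L, max)),
        features = data.frame(doublet_prob = dblProb),
        classProbs = classProbs)
}

#' Read a ground-truth label table
#'
#' Reads a two-column TSV (`barcode`, `label`) in which `label` is a donor id
#' or `"doublet"` and returns a named character vector of labels.
#'
#' @param path path to the TSV.
#' @return named character vector (names = barcodes).
#' @export
readGroundTruth <- function(path) {
    df <- .read_tsv(path)
    .require_columns(df, c("barcode", "label"), path)
    .check_unique_barcodes(df$barcode, path)
    stats::setNames(df$label, df$barcode)
}
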