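#' Read an MSAP band matrix
#'
#' Two dialects are supported.  \emph{long}: comma-separated with header
#' \code{sample_id,group,enzyme,replicate_of,<locus...>}, exactly two rows per
#' sample (enzyme \code{HPA} and \code{MSP}), cells \code{0}/\code{1}/
#' \code{NA}.  \emph{msap}: the layout consumed by the classic msap R tool —
#' first row holds the locus names, each further row is
#' \code{group,sample,enzyme,<0/1 cells>}; a \code{columns} override remaps
#' the three leading metadata columns for files that deviate.
#'
#' @param path file to read.
#' @param dialect \code{"long"} or \code{"msap"}.
#' @param columns named integer vector giving the positions of the
#'   \code{group}, \code{sample} and \code{enzyme} columns in the msap
#'   dialect.
#' @return A validated [MsapExperiment-class]; every sample has calls for
#'   both enzyme combinations.
#' @seealso [writeBandMatrix()]
#' @export
readBandMatrix <- function(path, dialect = c("long", "msap"),
                           columns = c(group = 1L, sample = 2L,
                                       enzyme = 3L)) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (dialect == "long")
        .readLong(path)
    else
        .readMsapDialect(path, columns)
}

.parseCells <- function(x, path) {
    x[is.na(x)] <- "NA"
    bad <- !(x %in% c("0", "1", "NA", ""))
    if (any(bad))
        stop(sprintf("unknown cell value(s) in %s: %s", path,
                     paste(unique(x[bad]), collapse = ", ")))
    out <- suppressWarnings(as.integer(x))
    out
}

.assembleExperiment <- function(sample, group, enzyme, cells, loci,
                                replicateOf = NULL, path = "input") {
    enzyme <- toupper(enzyme)
    if (any(!enzyme %in% c("HPA", "MSP")))
        stop("enzyme tokens must be HPA or MSP in ", path)
    samples <- unique(sample)
    hpaIdx <- match(samples, sample[enzyme == "HPA"])
    mspIdx <- match(samples, sample[enzyme == "MSP"])
    onlyOne <- samples[is.na(hpaIdx) | is.na(mspIdx)]
    if (length(onlyOne))
        stop("sample(s) present for only one enzyme combination: ",
             paste(onlyOne, collapse = ", "))
    if (anyDuplicated(paste(sample, enzyme)))
        stop("duplicated sample/enzyme rows in ", path)
    hpa <- t(cells[enzyme == "HPA", , drop = FALSE][hpaIdx, , drop = FALSE])
    msp <- t(cells[enzyme == "MSP", , drop = FALSE][mspIdx, , drop = FALSE])
    dimnames(hpa) <- dimnames(msp) <- list(loci, samples)
    grp <- group[match(samples, sample)]
    rep <- NULL
    if (!is.null(replicateOf)) {
        rep <- replicateOf[match(samples, sample)]
        rep[rep == ""] <- NA_character_
        if (all(is.na(rep)))
            rep <- NULL
    }
    MsapExperiment(hpa, msp, group = grp, replicateOf = rep)
}

.readLong <- function(path) {
    tab <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
    need <- c("sample_id", "group", "enzyme", "replicate_of")
    if (!all(need %in% colnames(tab)[seq_len(4L)]))
        stop("long dialect requires header columns ",
             paste(need, collapse = ","), " in ", path)
    loci <- colnames(tab)[-seq_len(4L)]
    cells <- matrix(NA_integer_, nrow(tab), length(loci))
    if (length(loci))
        cells <- matrix(.parseCells(unlist(tab[-seq_len(4L)],
                                           use.names = FALSE), path),
                        nrow(tab))
    .assembleExperiment(tab$sample_id, tab$group, tab$enzyme, cells, loci,
                        replicateOf = tab$replicate_of, path = path)
}

.readMsapDialect <- function(path, columns) {
    lines <- readLines(path)
    if (!length(lines))
        stop("empty file: ", path)
    split <- strsplit(lines, ",", fixed = TRUE)
    header <- split[[1L]]
    loci <- header[header != ""]
    body <- split[-1L]
    nmeta <- max(columns)
    cells <- matrix(NA_integer_, length(body), length(loci))
    meta <- matrix("", length(body), 3L,
                   dimnames = list(NULL, c("group", "sample", "enzyme")))
    for (i in seq_along(body)) {
        row <- body[[i]]
        if (length(row) != nmeta + length(loci))
            stop(sprintf("row %d of %s has %d fields, expected %d",
                         i + 1L, path, length(row), nmeta + length(loci)))
        meta[i, ] <- row[columns[c("group", "sample", "enzyme")]]
        if (length(loci))
            cells[i, ] <- .parseCells(row[-seq_len(nmeta)], path)
    }
    .assembleExperiment(meta[, "sample"], meta[, "group"], meta[, "enzyme"],
                        cells, loci, path = path)
}

#' Write an MSAP band matrix
#'
#' Writes a file that [readBandMatrix()] reads back to an equal dataset.
#' Missing calls are written as the literal token \code{NA}; output is UTF-8
#' with LF line endings.  The msap dialect cannot carry replicate links.
#'
#' @param x a [MsapExperiment-class] object.
#' @param path output file path.
#' @param dialect \code{"long"} or \code{"msap"}.
#' @return The path, invisibly.
#' @export
writeBandMatrix <- function(x, path, dialect = c("long", "msap")) {
    dialect <- match.arg(dialect)
    stopifnot(is(x, "MsapExperiment"))
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) stop("cannot write to ", path))
    on.exit(close(con))
    cd <- colData(x)
    rep <- if ("replicate_of" %in% colnames(cd)) cd$replicate_of
           else rep(NA_character_, ncol(x))
    rep[is.na(rep)] <- ""
    fmtCells <- function(m) {
        m <- format(m)          # "0"/"1"/"NA"
        gsub(" ", "", m, fixed = TRUE)
    }
    hpa <- fmtCells(t(presenceCalls(x, "hpa")))
    msp <- fmtCells(t(presenceCalls(x, "msp")))
    rows <- character(2L * ncol(x))
    if (dialect == "long") {
        header <- paste(c("sample_id", "group", "enzyme", "replicate_of",
                          rownames(x)), collapse = ",")
        for (i in seq_len(ncol(x))) {
            rows[2L * i - 1L] <- paste(c(colnames(x)[i], cd$group[i], "HPA",
                                         rep[i], hpa[i, ]), collapse = ",")
            rows[2L * i] <- paste(c(colnames(x)[i], cd$group[i], "MSP",
                                    rep[i], msp[i, ]), collapse = ",")
        }
    } else {
        header <- paste(rownames(x), collapse = ",")
        for (i in seq_len(ncol(x))) {
            rows[2L * i - 1L] <- paste(c(cd$group[i], colnames(x)[i], "HPA",
                                         hpa[i, ]), collapse = ",")
            rows[2L * i] <- paste(c(cd$group[i], colnames(x)[i], "MSP",
                                    msp[i, ]), collapse = ",")
        }
    }
    writeLines(c(header, rows), con, sep = "\n")
    invisible(path)
}

#' Estimate genotyping error from technical replicate pairs
#'
#' The standard dominant-marker (AFLP/MSAP) error-rate estimate: for each
#' primer combination, the number of discordant presence calls between
#' replicate pairs (both enzyme combinations pooled) divided by the number of
#' compared calls where neither member is missing.
#'
#' @param x a [MsapExperiment-class] with at least one replicate pair (see
#'   [replicatePairs()]).
#' @return Named numeric vector of error rates in [0, 1], one per primer
#'   combination (a single rate named \code{"all"} when loci carry no
#'   \code{primer_combo} annotation).
#' @export
estimateGenotypingError <- function(x) {
    pairs <- replicatePairs(x)
    if (!nrow(pairs))
        stop("no replicate pairs: cannot estimate genotyping error")
    combo <- rowData(x)$primer_combo
    if (is.null(combo))
        combo <- rep("all", nrow(x))
    hpa <- presenceCalls(x, "hpa")
    msp <- presenceCalls(x, "msp")
    out <- numeric(0)
    for (pc in unique(combo)) {
        sel <- combo == pc
        mism <- 0L
        comp <- 0L
        for (i in seq_len(nrow(pairs))) {
            for (m in list(hpa, msp)) {
                a <- m[sel, pairs[i, 1L]]
                b <- m[sel, pairs[i, 2L]]
                ok <- !is.na(a) & !is.na(b)
                comp <- comp + sum(ok)
                mism <- mism + sum(a[ok] != b[ok])
            }
        }
        out[pc] <- if (comp) mism / comp else NA_real_
    }
    out
}
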