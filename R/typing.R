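#' Call methylation types from two-enzyme band patterns
#'
#' The HpaII/MspI isoschizomers share the CCGG target but differ in
#' methylation sensitivity, so the pair of presence calls encodes the
#' methylation state of a locus: both bands present = type I (unmethylated);
#' MspI only = type II (internal cytosine methylation); HpaII only = type III
#' (hemi-methylated outer cytosine); neither = type IV (hypermethylated, or
#' target absent).  A cell is missing iff either enzyme call is missing.
#'
#' @param x a [MsapExperiment-class] object.
#' @return A [MethylationCalls-class] with assay \code{"type"} holding codes
#'   1--4.
#' @export
callMethylationTypes <- function(x) {
    stopifnot(is(x, "MsapExperiment"))
    h <- presenceCalls(x, "hpa")
    m <- presenceCalls(x, "msp")
    # (h,m): (1,1)->I, (0,1)->II, (1,0)->III, (0,0)->IV
    type <- 1L + (1L - h) + 2L * (1L - m)
    type[is.na(h) | is.na(m)] <- NA_integer_
    new("MethylationCalls", SummarizedExperiment(
        assays = list(type = type), colData = colData(x), rowData = rowData(x)))
}

#' Methylation type matrix
#'
#' @param x a [MethylationCalls-class] object.
#' @param labels return roman labels \code{"I".."IV"} instead of codes 1--4.
#' @return Loci x samples matrix of type codes (or labels) with NA for
#'   missing cells.
#' @export
setGeneric("typeCalls", function(x, labels = FALSE) standardGeneric("typeCalls"))

#' @rdname typeCalls
#' @export
setMethod("typeCalls", "MethylationCalls", function(x, labels = FALSE) {
    tp <- assay(x, "type")
    if (labels) {
        lab <- matrix(c("I", "II", "III", "IV")[tp], nrow(tp),
                      dimnames = dimnames(tp))
        return(lab)
    }
    tp
})

#' Classify loci as methylation-susceptible and extract polymorphic MSL
#'
#' A locus is methylation-susceptible (MSL) iff the proportion of non-missing
#' samples showing a methylation-indicative type (II, III or IV) strictly
#' exceeds \code{errorThreshold}; otherwise it is non-methylated (NML).  MSL
#' cells are binarized as methylated (types II/III/IV) vs unmethylated
#' (type I); type IV is counted as methylated even though the double-absence
#' pattern can also reflect target loss (documented caveat of the marker
#' system).  An MSL is polymorphic iff each binary state occurs in strictly
#' more than \code{errorThreshold} of its non-missing samples; only
#' polymorphic MSL enter the binary matrix.  Loci with all cells missing are
#' excluded with a message.
#'
#' @param x a [MethylationCalls-class] object.
#' @param errorThreshold fraction in [0, 1); default 0.05, aligned with
#'   typical per-primer genotyping error.
#' @return A list with \code{classification} (data.frame: locus, n_typed,
#'   prop_methylated, is_msl, is_polymorphic) and \code{msl} (a
#'   [MslBinaryMatrix-class] of the polymorphic MSL).
#' @export
classifyLoci <- function(x, errorThreshold = 0.05) {
    stopifnot(is(x, "MethylationCalls"))
    if (!is.numeric(errorThreshold) || length(errorThreshold) != 1L ||
        errorThreshold < 0 || errorThreshold >= 1)
        stop("'errorThreshold' must be a single value in [0, 1)")
    tp <- assay(x, "type")
    nTyped <- rowSums(!is.na(tp))
    allMissing <- nTyped == 0L
    if (any(allMissing))
        message(sum(allMissing), " locus/loci with all cells missing ",
                "excluded: ", paste(rownames(tp)[allMissing], collapse = ", "))
    meth <- (tp >= 2L) * 1L             # NA propagates
    nMeth <- rowSums(meth == 1L, na.rm = TRUE)
    nUnmeth <- rowSums(meth == 0L, na.rm = TRUE)
    propMeth <- ifelse(nTyped > 0L, nMeth / nTyped, NA_real_)
    isMsl <- !allMissing & propMeth > errorThreshold
    isPoly <- isMsl & (nMeth / nTyped > errorThreshold) &
        (nUnmeth / nTyped > errorThreshold)
    classification <- data.frame(
        locus = rownames(tp), n_typed = as.integer(nTyped),
        prop_methylated = propMeth, is_msl = isMsl,
        is_polymorphic = isPoly, row.names = NULL,
        stringsAsFactors = FALSE)
    keep <- which(isPoly)
    mslAssay <- matrix(as.integer(meth[keep, , drop = FALSE]),
                       nrow = length(keep), ncol = ncol(tp),
                       dimnames = list(rownames(tp)[keep], colnames(tp)))
    msl <- new("MslBinaryMatrix", SummarizedExperiment(
        assays = list(methylated = mslAssay),
        colData = colData(x)))
    list(classification = classification, msl = msl)
}

#' Binary methylation states of polymorphic MSL
#'
#' @param x a [MslBinaryMatrix-class] object.
#' @return Loci x samples 0/1/NA matrix (1 = methylated).
#' @export
setGeneric("mslStates", function(x) standardGeneric("mslStates"))

#' @rdname mslStates
#' @export
setMethod("mslStates", "MslBinaryMatrix", function(x) assay(x, "methylated"))

#' Per-sample global methylation ratio
#'
#' Ratio of methylated to scorable informative loci:
#' (types II + III) / (types I + II + III).  Type IV is excluded from both
#' numerator and denominator because double absence cannot be distinguished
#' from target loss; missing cells are excluded too.
#'
#' @param x a [MethylationCalls-class] object.
#' @return Named numeric per-sample ratio in [0, 1].  A sample with no
#'   scorable informative locus (denominator 0) is an error.
#' @export
globalMethylationRatio <- function(x) {
    stopifnot(is(x, "MethylationCalls"))
    tp <- assay(x, "type")
    num <- colSums(tp == 2L | tp == 3L, na.rm = TRUE)
    den <- colSums(tp <= 3L, na.rm = TRUE)
    if (any(den == 0L))
        stop("global methylation ratio undefined (no scorable informative ",
             "loci) for sample(s): ",
             paste(colnames(tp)[den == 0L], collapse = ", "))
    num / den
}

#' Per-group counts of methylation types
#'
#' @param x a [MethylationCalls-class] object.
#' @return Groups x 4 integer matrix of counts of types I--IV over
#'   non-missing cells; each row sums to the group's non-missing cell count.
#' @export
bandTypeFrequencies <- function(x) {
    stopifnot(is(x, "MethylationCalls"))
    tp <- assay(x, "type")
    grp <- sampleGroups(x)
    lv <- sort(unique(grp))
    out <- matrix(0L, length(lv), 4L,
                  dimnames = list(lv, c("I", "II", "III", "IV")))
    for (g in lv) {
        cells <- tp[, grp == g, drop = FALSE]
        out[g, ] <- tabulate(cells[!is.na(cells)], 4L)
    }
    out
}
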