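#' Construct an MsapExperiment
#'
#' @param hpa,msp integer matrices of band calls (loci in rows, samples in
#'   columns) for the HpaII+EcoRI and MspI+EcoRI digests; cells 0/1/NA.  Both
#'   must share dimensions, row (locus) and column (sample) names.
#' @param group character or factor of per-sample group labels.
#' @param replicateOf optional character per sample: the sample id this sample
#'   is a technical replicate of, or NA.
#' @param primerCombo optional character per locus naming the primer
#'   combination the locus was amplified with.
#' @return A [MsapExperiment-class] object.
#' @examples
#' h <- matrix(1L, 3, 2, dimnames = list(paste0("L", 1:3), c("s1", "s2")))
#' m <- h
#' MsapExperiment(h, m, group = c("A", "B"))
#' @export
MsapExperiment <- function(hpa, msp, group, replicateOf = NULL,
                           primerCombo = NULL) {
    hpa <- .asCallMatrix(hpa, "hpa")
    msp <- .asCallMatrix(msp, "msp")
    if (!identical(dim(hpa), dim(msp)))
        stop("'hpa' and 'msp' must have identical dimensions")
    if (is.null(rownames(hpa)))
        rownames(hpa) <- rownames(msp) <- sprintf("L%04d", seq_len(nrow(hpa)))
    if (is.null(colnames(hpa)))
        colnames(hpa) <- colnames(msp) <- sprintf("S%03d", seq_len(ncol(hpa)))
    if (!identical(rownames(hpa), rownames(msp)))
        stop("'hpa' and 'msp' must have identical locus ordering")
    if (!identical(colnames(hpa), colnames(msp)))
        stop("'hpa' and 'msp' must have identical sample ordering")
    if (length(group) != ncol(hpa))
        stop("'group' must have one label per sample")
    cd <- DataFrame(group = as.character(group), row.names = colnames(hpa))
    if (!is.null(replicateOf)) {
        if (length(replicateOf) != ncol(hpa))
            stop("'replicateOf' must have one entry per sample")
        cd$replicate_of <- as.character(replicateOf)
    }
    rd <- DataFrame(row.names = rownames(hpa))
    if (!is.null(primerCombo)) {
        if (length(primerCombo) != nrow(hpa))
            stop("'primerCombo' must have one entry per locus")
        rd$primer_combo <- as.character(primerCombo)
    }
    new("MsapExperiment", SummarizedExperiment(
        assays = list(hpa = hpa, msp = msp), colData = cd, rowData = rd))
}

.asCallMatrix <- function(m, what) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    bad <- .validCallMatrix(m, what)
    if (!is.null(bad))
        stop(bad)
    m
}

#' Per-sample group labels
#'
#' @param x a [MsapExperiment-class], [MethylationCalls-class] or
#'   [MslBinaryMatrix-class] object.
#' @return Character vector of group labels, named by sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
    g <- colData(x)$group
    names(g) <- colnames(x)
    g
})

#' Band presence calls for one digest
#'
#' @param x a [MsapExperiment-class] object.
#' @param enzyme \code{"hpa"} or \code{"msp"}.
#' @return Integer matrix (loci x samples) of 0/1/NA calls.
#' @export
setGeneric("presenceCalls",
    function(x, enzyme = c("hpa", "msp")) standardGeneric("presenceCalls"))

#' @rdname presenceCalls
#' @export
setMethod("presenceCalls", "MsapExperiment", function(x, enzyme) {
    assay(x, match.arg(enzyme, c("hpa", "msp")))
})

#' Technical replicate pairs
#'
#' Pairs are taken from the \code{replicate_of} column of \code{colData}:
#' a sample with a non-missing \code{replicate_of} is paired with the sample
#' it names.
#'
#' @param x a [MsapExperiment-class] object.
#' @return Two-column character matrix of sample-id pairs (possibly 0 rows).
#' @export
setGeneric("replicatePairs", function(x) standardGeneric("replicatePairs"))

#' @rdname replicatePairs
#' @export
setMethod("replicatePairs", "MsapExperiment", function(x) {
    cd <- colData(x)
    out <- matrix(character(), 0, 2,
                  dimnames = list(NULL, c("sample", "replicate")))
    if (!"replicate_of" %in% colnames(cd))
        return(out)
    has <- !is.na(cd$replicate_of) & cd$replicate_of != ""
    if (!any(has))
        return(out)
    ref <- cd$replicate_of[has]
    missing <- setdiff(ref, colnames(x))
    if (length(missing))
        stop("replicate_of refers to unknown sample(s): ",
             paste(missing, collapse = ", "))
    cbind(sample = ref, replicate = colnames(x)[has])
})

setMethod("show", "MsapExperiment", function(object) {
    g <- table(sampleGroups(object))
    cat(sprintf("MsapExperiment: %d loci x %d samples\n",
                nrow(object), ncol(object)))
    cat("  groups:", paste(sprintf("%s (n=%d)", names(g), as.integer(g)),
                           collapse = ", "), "\n")
    nrep <- nrow(replicatePairs(object))
    if (nrep)
        cat("  technical replicate pairs:", nrep, "\n")
})

setMethod("show", "MethylationCalls", function(object) {
    cat(sprintf("MethylationCalls: %d loci x %d samples\n",
                nrow(object), ncol(object)))
    tp <- assay(object, "type")
    tab <- tabulate(tp[!is.na(tp)], 4)
    cat(sprintf("  type counts  I: %d  II: %d  III: %d  IV: %d  (NA: %d)\n",
                tab[1], tab[2], tab[3], tab[4], sum(is.na(tp))))
})

setMethod("show", "MslBinaryMatrix", function(object) {
    cat(sprintf("MslBinaryMatrix: %d polymorphic MSL x %d samples\n",
                nrow(object), ncol(object)))
})

setMethod("show", "AmovaResult", function(object) {
    cat("AMOVA\n")
    tab <- data.frame(
        d.f. = object@df,
        SSD = object@ssd,
        MSD = c(object@msd, NA),
        Variance = c(object@sigma2, NA),
        row.names = c("Among groups", "Within groups", "Total"),
        check.names = FALSE)
    print(format(tab, digits = 6, na.encode = FALSE))
    cat(sprintf("n0 = %.6g   Phi_ST = %.6g\n", object@n0, object@phiST))
    if (object@nPermutations > 0L)
        cat(sprintf("permutation p = %.6g (%d permutations)\n",
                    object@pPerm, object@nPermutations))
})

setMethod("show", "PcoaResult", function(object) {
    k <- ncol(object@coordinates)
    cat(sprintf("PCoA: %d samples, %d retained axes\n",
                nrow(object@coordinates), k))
    if (k)
        cat("  % variance:",
            paste(sprintf("%.1f", object@pctVariance[seq_len(min(k, 5))]),
                  collapse = ", "),
            if (k > 5) "..." else "", "\n")
})

setMethod("show", "QpcrExperiment", function(object) {
    m <- object@measurements
    cat(sprintf("QpcrExperiment: %d measurements, %d genes, %d samples\n",
                nrow(m), length(unique(m$gene)), length(unique(m$sample))))
    cat("  reference genes:", paste(object@referenceGenes, collapse = ", "),
        "\n")
})

#' Long-format Cq measurements
#'
#' @param x a [QpcrExperiment-class] object.
#' @return data.frame with columns sample, group, gene, cq, efficiency.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname measurements
#' @export
setMethod("measurements", "QpcrExperiment", function(x) x@measurements)

#' Reference gene labels
#'
#' @param x a [QpcrExperiment-class] object.
#' @return Character vector of length two.
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' @rdname referenceGenes
#' @export
setMethod("referenceGenes", "QpcrExperiment", function(x) x@referenceGenes)
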