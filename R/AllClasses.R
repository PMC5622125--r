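#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<- rowData
NULL

.validCallMatrix <- function(m, what) {
    if (!is.matrix(m))
        return(sprintf("'%s' must be a matrix", what))
    bad <- !(m %in% c(0L, 1L) | is.na(m))
    if (any(bad))
        return(sprintf("'%s' contains values other than 0, 1, NA", what))
    NULL
}

#' MsapExperiment: MSAP band calls for two isoschizomer digests
#'
#' Container for a methylation-sensitive amplified polymorphism (MSAP)
#' experiment: one band presence/absence call per locus per sample for each of
#' the two enzyme combinations (HpaII+EcoRI and MspI+EcoRI).  Loci are rows,
#' samples are columns, following the SummarizedExperiment convention.  The
#' two assays are named \code{"hpa"} and \code{"msp"}; cells are 1 (band
#' present), 0 (band absent) or \code{NA} (missing call).  \code{colData}
#' carries the per-sample \code{group} label and an optional
#' \code{replicate_of} column linking technical replicates; \code{rowData} may
#' carry a \code{primer_combo} label per locus.
#'
#' @export
setClass("MsapExperiment", contains = "SummarizedExperiment")

setValidity("MsapExperiment", function(object) {
    msgs <- character()
    if (!all(c("hpa", "msp") %in% assayNames(object)))
        msgs <- c(msgs, "assays 'hpa' and 'msp' are required")
    else {
        msgs <- c(msgs, .validCallMatrix(assay(object, "hpa"), "hpa"),
                        .validCallMatrix(assay(object, "msp"), "msp"))
    }
    if (!"group" %in% colnames(colData(object)))
        msgs <- c(msgs, "colData must contain a 'group' column")
    else if (anyNA(colData(object)$group))
        msgs <- c(msgs, "every sample needs a group label")
    if (length(msgs)) msgs else TRUE
})

#' MethylationCalls: per-sample, per-locus methylation types
#'
#' Result of [callMethylationTypes()].  Single assay \code{"type"} holding
#' integer codes 1--4 for methylation types I--IV (or \code{NA} where either
#' enzyme call was missing).  Type I = unmethylated (both digests cut),
#' II = internal cytosine methylation (MspI only), III = hemi-methylated outer
#' cytosine (HpaII only), IV = hypermethylated or absent target (neither).
#'
#' @export
setClass("MethylationCalls", contains = "SummarizedExperiment")

setValidity("MethylationCalls", function(object) {
    if (!"type" %in% assayNames(object))
        return("assay 'type' is required")
    tp <- assay(object, "type")
    if (any(!(tp %in% 1:4 | is.na(tp))))
        return("'type' cells must be integer codes 1..4 or NA")
    if (!"group" %in% colnames(colData(object)))
        return("colData must contain a 'group' column")
    TRUE
})

#' MslBinaryMatrix: binary methylation states at polymorphic MSL
#'
#' Result of [classifyLoci()]: only polymorphic methylation-susceptible loci
#' are retained.  Single assay \code{"methylated"} with 1 = methylated
#' (types II/III/IV), 0 = unmethylated (type I), \code{NA} = missing.  Every
#' retained locus shows both states among its non-missing cells.
#'
#' @export
setClass("MslBinaryMatrix", contains = "SummarizedExperiment")

setValidity("MslBinaryMatrix", function(object) {
    if (!"methylated" %in% assayNames(object))
        return("assay 'methylated' is required")
    m <- assay(object, "methylated")
    bad <- .validCallMatrix(m, "methylated")
    if (!is.null(bad))
        return(bad)
    if (nrow(m)) {
        ones  <- rowSums(m == 1L, na.rm = TRUE)
        zeros <- rowSums(m == 0L, na.rm = TRUE)
        if (any(ones == 0L | zeros == 0L))
            return("every retained locus must show both binary states")
    }
    TRUE
})

#' AmovaResult: analysis of molecular variance for one comparison
#'
#' Degrees of freedom, sums and mean squares of squared deviations, the
#' weighted average group size n0, variance components (among / within,
#' negative components retained), the differentiation index Phi_ST and, when
#' permutations were run, the permutation p-value.
#'
#' @slot df integer named vector (among, within, total).
#' @slot ssd numeric named vector of sums of square deviations.
#' @slot msd numeric named vector of mean square deviations (among, within).
#' @slot n0 numeric, weighted average group size.
#' @slot sigma2 numeric named vector of variance components (among, within).
#' @slot phiST numeric differentiation index.
#' @slot nPermutations integer, 0 when no test was run.
#' @slot pPerm numeric permutation p-value, \code{NA_real_} when untested.
#' @slot groupSizes integer named vector of group sizes.
#' @export
setClass("AmovaResult",
    representation(df = "integer", ssd = "numeric", msd = "numeric",
                   n0 = "numeric", sigma2 = "numeric", phiST = "numeric",
                   nPermutations = "integer", pPerm = "numeric",
                   groupSizes = "integer"))

setValidity("AmovaResult", function(object) {
    msgs <- character()
    if (!identical(names(object@df), c("among", "within", "total")))
        msgs <- c(msgs, "df must be named (among, within, total)")
    if (abs(object@ssd[["total"]] -
            (object@ssd[["among"]] + object@ssd[["within"]])) >
        1e-9 * max(1, abs(object@ssd[["total"]])))
        msgs <- c(msgs, "ssd_total must equal ssd_among + ssd_within")
    if (is.finite(object@phiST) && object@phiST > 1 + 1e-12)
        msgs <- c(msgs, "phiST cannot exceed 1")
    if (length(msgs)) msgs else TRUE
})

#' PcoaResult: principal coordinates ordination
#'
#' Classical (metric) scaling of a squared-distance matrix.  Coordinates are
#' kept for positive-eigenvalue axes only, ordered by decreasing eigenvalue;
#' \code{pctVariance} is the percentage of (positive) eigenvalue mass per
#' retained axis and sums to 100.
#'
#' @slot coordinates samples x axes numeric matrix.
#' @slot eigenvalues numeric, all eigenvalues (retained and dropped).
#' @slot pctVariance numeric, percentage of variance per retained axis.
#' @export
setClass("PcoaResult",
    representation(coordinates = "matrix", eigenvalues = "numeric",
                   pctVariance = "numeric"))

#' QpcrExperiment: quantification cycles with primer efficiencies
#'
#' Long-format Cq measurements, one row per (sample, gene), plus the two
#' reference genes used for normalization.  Efficiency E is the per-gene
#' amplification efficiency in (0, 1], 1 meaning perfect doubling per cycle.
#'
#' @slot measurements data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{cq}, \code{efficiency}.
#' @slot referenceGenes character vector of exactly two gene labels.
#' @export
setClass("QpcrExperiment",
    representation(measurements = "data.frame", referenceGenes = "character"))

setValidity("QpcrExperiment", function(object) {
    msgs <- character()
    need <- c("sample", "group", "gene", "cq", "efficiency")
    if (!all(need %in% colnames(object@measurements)))
        msgs <- c(msgs, paste("measurements needs columns:",
                              paste(need, collapse = ", ")))
    if (length(object@referenceGenes) != 2L)
        msgs <- c(msgs, "exactly two reference genes are required")
    else {
        m <- object@measurements
        if (!all(object@referenceGenes %in% m$gene))
            msgs <- c(msgs, "reference genes absent from measurements")
        else {
            for (rg in object@referenceGenes) {
                have <- unique(m$sample[m$gene == rg])
                if (!all(unique(m$sample) %in% have))
                    msgs <- c(msgs, sprintf(
                        "every sample needs a Cq for reference gene '%s'", rg))
            }
        }
        if (any(m$efficiency <= 0 | m$efficiency > 1))
            msgs <- c(msgs, "efficiencies must lie in (0, 1]")
    }
    if (length(msgs)) msgs else TRUE
})
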