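#' Efficiency-corrected quantification cycle
#'
#' Rescales a Cq measured with amplification efficiency E to the perfect-
#' doubling (base-2) scale: \eqn{Cq_E = Cq \cdot \log(1+E)/\log 2}.  With
#' E = 1 the Cq is unchanged.
#'
#' @param cq quantification cycle(s), in cycles (> 0).
#' @param efficiency amplification efficiency E in (0, 1] (scalar or
#'   per-value).
#' @return Corrected Cq in cycles.
#' @examples
#' efficiencyCorrect(20, 0.9)   # 20 * log2(1.9) ~= 18.52
#' @export
efficiencyCorrect <- function(cq, efficiency) {
    if (!is.numeric(efficiency) || any(is.na(efficiency)) ||
        any(efficiency <= 0 | efficiency > 1))
        stop("'efficiency' must lie in (0, 1]")
    if (!is.numeric(cq) || any(is.na(cq)) || any(cq <= 0))
        stop("'cq' must be positive")
    cq * log(1 + efficiency) / log(2)
}

#' Reference-normalized delta-Cq values
#'
#' Per sample and target gene:
#' \eqn{\Delta Cq = Cq_E(target) - \frac{1}{2}(Cq_E(ref_1) + Cq_E(ref_2))}.
#' The arithmetic mean of corrected Cq equals the geometric mean of the two
#' reference genes on the expression (\eqn{2^{-Cq}}) scale.
#'
#' @param x a [QpcrExperiment-class] object.
#' @return data.frame with columns sample, group, gene, dcq (target genes
#'   only).
#' @export
deltaCq <- function(x) {
    stopifnot(is(x, "QpcrExperiment"))
    m <- measurements(x)
    refs <- referenceGenes(x)
    m$cq_e <- efficiencyCorrect(m$cq, m$efficiency)
    isRef <- m$gene %in% refs
    refTab <- m[isRef, ]
    refMean <- tapply(refTab$cq_e, refTab$sample, function(v) {
        if (length(v) != 2L)
            stop("each sample needs exactly one Cq per reference gene")
        mean(v)
    })
    tgt <- m[!isRef, ]
    missRef <- setdiff(tgt$sample, names(refMean))
    if (length(missRef))
        stop("missing reference Cq for sample(s): ",
             paste(missRef, collapse = ", "))
    data.frame(sample = tgt$sample, group = tgt$group, gene = tgt$gene,
               dcq = tgt$cq_e - as.numeric(refMean[tgt$sample]),
               stringsAsFactors = FALSE)
}

#' Fold change with propagated error
#'
#' The 2^-ddCq estimate: \eqn{\Delta\Delta Cq} is the difference of group
#' mean \eqn{\Delta Cq} values (treatment minus control), the log2 fold
#' change is \eqn{-\Delta\Delta Cq}, and its standard error combines the two
#' group standard errors in quadrature,
#' \eqn{SE = \sqrt{SE_t^2 + SE_c^2}}.  The confidence interval on the log2
#' scale uses a Student-t quantile with Welch-Satterthwaite degrees of
#' freedom for the quadrature SE, keeping the interval calibrated at the
#' small replicate numbers (n = 4) typical of qPCR designs.
#'
#' @param dcqTreatment,dcqControl numeric vectors of per-replicate dCq values
#'   (>= 2 each).
#' @param confidence confidence level for the interval, default 0.95.
#' @return One-row data.frame: ddcq, log2fc, fold_change, se, ci_lo, ci_hi,
#'   n_treatment, n_control.
#' @export
foldChange <- function(dcqTreatment, dcqControl, confidence = 0.95) {
    if (length(dcqTreatment) < 2L || length(dcqControl) < 2L)
        stop("need >= 2 dCq values per group")
    ddcq <- mean(dcqTreatment) - mean(dcqControl)
    vt <- stats::var(dcqTreatment) / length(dcqTreatment)
    vc <- stats::var(dcqControl) / length(dcqControl)
    se <- sqrt(vt + vc)
    # Welch-Satterthwaite df for the quadrature SE
    dfWS <- if (se > 0)
        (vt + vc)^2 / (vt^2 / (length(dcqTreatment) - 1L) +
                       vc^2 / (length(dcqControl) - 1L))
    else length(dcqTreatment) + length(dcqControl) - 2L
    q <- stats::qt(1 - (1 - confidence) / 2, df = dfWS)
    log2fc <- -ddcq
    data.frame(ddcq = ddcq, log2fc = log2fc, fold_change = 2^log2fc,
               se = se, df_se = dfWS,
               ci_lo = log2fc - q * se, ci_hi = log2fc + q * se,
               n_treatment = length(dcqTreatment),
               n_control = length(dcqControl))
}

#' Relative-expression tests across configured comparisons
#'
#' For each gene and (treatment, control) group pair: fold change with
#' propagated error via [foldChange()], a two-tailed Student t test on the
#' dCq values (pooled variance by default, Welch behind a flag), and Storey
#' q-values computed jointly across all comparisons in the batch.  Normality
#' (Shapiro-Wilk per group) and homoscedasticity (Levene) are evaluated and
#' reported as gate columns but do not switch the test.
#'
#' @param dcq data.frame from [deltaCq()].
#' @param comparisons list of \code{c(treatment, control)} group-label pairs;
#'   default: every non-first group vs the first group (alphabetically).
#' @param confidence confidence level for intervals.
#' @param varEqual pooled-variance Student t (default) or Welch when FALSE.
#' @param genes optional subset of genes.
#' @return data.frame with one row per gene x comparison: fold-change fields,
#'   t, df, p, q, shapiro_p_treatment, shapiro_p_control, levene_p.
#' @export
expressionTests <- function(dcq, comparisons = NULL, confidence = 0.95,
                            varEqual = TRUE, genes = NULL) {
    stopifnot(all(c("group", "gene", "dcq") %in% colnames(dcq)))
    lv <- sort(unique(dcq$group))
    if (is.null(comparisons)) {
        if (length(lv) < 2L)
            stop("need >= 2 groups")
        comparisons <- lapply(lv[-1L], function(g) c(g, lv[1L]))
    }
    if (is.null(genes))
        genes <- sort(unique(dcq$gene))
    rows <- list()
    for (cmp in comparisons) {
        if (length(cmp) != 2L || !all(cmp %in% lv))
            stop("each comparison must name two groups present in the data: ",
                 paste(cmp, collapse = " vs "))
        for (g in genes) {
            xt <- dcq$dcq[dcq$group == cmp[1L] & dcq$gene == g]
            xc <- dcq$dcq[dcq$group == cmp[2L] & dcq$gene == g]
            if (length(xt) < 2L || length(xc) < 2L)
                stop(sprintf("gene %s, comparison %s vs %s: need >= 2 ",
                             g, cmp[1L], cmp[2L]),
                     "replicates per group")
            fc <- foldChange(xt, xc, confidence)
            tt <- .studentT(xt, xc, varEqual)
            sw <- function(v) {
                if (length(v) < 3L || stats::var(v) == 0)
                    return(NA_real_)
                stats::shapiro.test(v)$p.value
            }
            swT <- sw(xt)
            swC <- sw(xc)
            lev <- tryCatch(car::leveneTest(
                c(xt, xc), factor(rep(c("t", "c"), c(length(xt),
                                                     length(xc)))))[1L,
                "Pr(>F)"], error = function(e) NA_real_)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(gene = g, treatment = cmp[1L], control = cmp[2L],
                           stringsAsFactors = FALSE),
                fc,
                data.frame(t = tt$t, df = tt$df, p = tt$p,
                           shapiro_p_treatment = swT,
                           shapiro_p_control = swC, levene_p = lev))
        }
    }
    out <- do.call(rbind, rows)
    out$q <- storeyQvalues(out$p)
    gate <- stats::na.omit(c(out$shapiro_p_treatment, out$shapiro_p_control,
                             out$levene_p))
    if (length(gate) && any(gate < 0.05))
        message("normality/homoscedasticity gate: ", sum(gate < 0.05),
                " of ", length(gate),
                " checks below 0.05 (tests reported unchanged)")
    out
}

# Two-tailed two-sample t; handles the degenerate zero-variance case the
# way the contract requires (t = 0, p = 1 for identical constant groups).
.studentT <- function(x, y, varEqual = TRUE) {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y))
            return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
        return(list(t = sign(mean(x) - mean(y)) * Inf,
                    df = length(x) + length(y) - 2L, p = 0))
    }
    tt <- stats::t.test(x, y, var.equal = varEqual)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Morphometric group tests
#'
#' Rank-based tests for body weight/length comparisons: Kruskal-Wallis (with
#' tie correction) for multi-group designs, two-sided Wilcoxon rank-sum for
#' two groups.
#'
#' @param valuesByGroup named list of numeric vectors, one per group.
#' @param design \code{"multi_group"} or \code{"two_group"}.
#' @return list with \code{statistic} (chi-squared or W), \code{p},
#'   \code{method}.
#' @export
morphometricTests <- function(valuesByGroup,
                              design = c("multi_group", "two_group")) {
    design <- match.arg(design)
    if (any(!vapply(valuesByGroup, length, 1L)))
        stop("every group needs at least one value")
    if (design == "multi_group") {
        if (length(valuesByGroup) < 2L)
            stop("need >= 2 groups")
        kt <- stats::kruskal.test(valuesByGroup)
        stat <- unname(kt$statistic)
        p <- kt$p.value
        if (is.nan(stat) && length(unique(unlist(valuesByGroup))) == 1L) {
            # all observations tied: no rank variation, chi-squared is 0
            stat <- 0
            p <- 1
        }
        list(statistic = stat, p = p, method = "Kruskal-Wallis")
    } else {
        if (length(valuesByGroup) != 2L)
            stop("two_group design needs exactly 2 groups")
        wt <- stats::wilcox.test(valuesByGroup[[1L]], valuesByGroup[[2L]],
                                 exact = NULL)
        list(statistic = unname(wt$statistic), p = wt$p.value,
             method = "Wilcoxon rank sum")
    }
}
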