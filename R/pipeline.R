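#' Read a run configuration
#'
#' Flat YAML file describing a full analysis run.  Recognized keys (MSAP):
#' \code{msap_input}, \code{dialect}, \code{comparisons} (mapping of
#' comparison name to a list of >= 2 group labels), \code{error_threshold},
#' \code{alpha}, \code{n_permutations}, \code{seed}, \code{out_dir}.
#' qPCR keys: \code{qpcr_input}, \code{reference_genes},
#' \code{qpcr_comparisons} (list of \code{[treatment, control]} pairs),
#' \code{confidence}.
#'
#' @param path YAML file.
#' @return Named list of class \code{"msapRunConfig"} with defaults filled
#'   in.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(dialect = "long", error_threshold = 0.05, alpha = 0.05,
                     n_permutations = 10000L, seed = 1L, confidence = 0.95)
    for (k in names(defaults))
        if (is.null(cfg[[k]]))
            cfg[[k]] <- defaults[[k]]
    structure(cfg, class = "msapRunConfig")
}

.logLine <- function(log, ...) {
    line <- paste0(...)
    message(line)
    cat(line, "\n", file = log, append = TRUE, sep = "")
}

#' Run the full MSAP differentiation analysis
#'
#' Orchestrates one or more comparison rounds from a single configuration.
#' Each comparison is an independent locus-classification round restricted to
#' its groups (polymorphic-MSL sets therefore differ between comparisons by
#' design), followed by: AMOVA with permutation test (overall + pairwise),
#' PCoA, per-locus Fisher tests with BH-FDR, Gower-UPGMA clustering of the
#' significant loci, global methylation ratios and band-type frequencies.
#' All randomness derives from the single config seed; a rerun with the same
#' config and seed produces byte-identical tables.
#'
#' @param config path to a YAML config, or a list as returned by
#'   [readRunConfig()].
#' @return Invisibly, a named list (one element per comparison) of result
#'   bundles; files are written under \code{out_dir/<comparison>/}.
#' @export
runMsapAnalysis <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    if (is.null(config$msap_input) || is.null(config$out_dir) ||
        is.null(config$comparisons))
        stop("config must provide msap_input, out_dir and comparisons")
    dataset <- readBandMatrix(config$msap_input, dialect = config$dialect)
    have <- unique(sampleGroups(dataset))
    # validate every comparison before any computation
    for (nm in names(config$comparisons)) {
        gs <- unlist(config$comparisons[[nm]])
        if (length(gs) < 2L)
            stop("comparison '", nm, "' must reference >= 2 group labels")
        unknown <- setdiff(gs, have)
        if (length(unknown))
            stop("comparison '", nm, "' references unknown group(s): ",
                 paste(unknown, collapse = ", "))
    }
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(config$out_dir, "run.log")
    cat("", file = log)
    .logLine(log, "msapDiff ",
             as.character(utils::packageVersion("msapDiff")),
             " MSAP analysis")
    .logLine(log, "seed=", config$seed,
             " error_threshold=", config$error_threshold,
             " alpha=", config$alpha,
             " n_permutations=", config$n_permutations)
    out <- list()
    for (nm in names(config$comparisons)) {
        gs <- unlist(config$comparisons[[nm]])
        .logLine(log, "comparison '", nm, "': ", paste(gs, collapse = " vs "))
        sub <- dataset[, sampleGroups(dataset) %in% gs]
        out[[nm]] <- .runComparison(sub, nm, config, log)
    }
    invisible(out)
}

.runComparison <- function(sub, name, config, log) {
    dir <- file.path(config$out_dir, name)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    types <- callMethylationTypes(sub)
    cls <- classifyLoci(types, errorThreshold = config$error_threshold)
    writeTsv(cls$classification, file.path(dir, "locus_classification.tsv"))
    .logLine(log, "  ", sum(cls$classification$is_msl), " MSL / ",
             nrow(cls$classification), " loci; ",
             nrow(cls$msl), " polymorphic MSL")

    grp <- sampleGroups(cls$msl)
    d2 <- msapDistance(cls$msl)
    am <- amova(d2, grp, nPermutations = config$n_permutations,
                seed = deriveSeed(config$seed, paste0("amova:", name)))
    writeAmovaTable(am, file.path(dir, "amova.tsv"))
    .logLine(log, "  Phi_ST = ", signif(am@phiST, 4), ", p = ",
             signif(am@pPerm, 4))
    pw <- pairwiseGroupAmova(d2, grp,
                             nPermutations = config$n_permutations,
                             seed = deriveSeed(config$seed,
                                               paste0("pairwise:", name)))
    writeTsv(pw, file.path(dir, "amova_pairwise.tsv"))

    pc <- runPcoa(d2)
    pcTab <- data.frame(sample = rownames(pc@coordinates), group = grp,
                        pc@coordinates[, seq_len(min(4L,
                            ncol(pc@coordinates))), drop = FALSE],
                        stringsAsFactors = FALSE)
    writeTsv(pcTab, file.path(dir, "pcoa_coordinates.tsv"))
    writeTsv(data.frame(axis = seq_along(pc@pctVariance),
                        pct_variance = pc@pctVariance),
             file.path(dir, "pcoa_variance.tsv"))

    lt <- locusFisherTests(cls$msl, alpha = config$alpha,
                           seed = deriveSeed(config$seed,
                                             paste0("fisher:", name)))
    writeTsv(lt, file.path(dir, "locus_tests.tsv"))
    sig <- lt$locus[lt$significant]
    .logLine(log, "  significant polymorphic MSL: ", length(sig), "/",
             nrow(lt), " at FDR < ", config$alpha)
    if (length(sig) >= 2L) {
        gd <- gowerDistance(types, loci = sig)
        tree <- upgmaCluster(gd)
        writeNewick(tree, file.path(dir, "significant_loci.nwk"))
        heat <- typeCalls(types, labels = TRUE)[
            tree$labels[tree$order], , drop = FALSE]
        writeTsv(data.frame(locus = rownames(heat), heat, check.names = FALSE,
                            stringsAsFactors = FALSE),
                 file.path(dir, "heatmap_matrix.tsv"))
    }
    ratios <- globalMethylationRatio(types)
    writeTsv(data.frame(sample = names(ratios), group = grp,
                        global_methylation = as.numeric(ratios),
                        stringsAsFactors = FALSE),
             file.path(dir, "global_methylation.tsv"))
    freq <- bandTypeFrequencies(types)
    writeTsv(data.frame(group = rownames(freq), freq, check.names = FALSE,
                        stringsAsFactors = FALSE),
             file.path(dir, "band_type_frequencies.tsv"))
    list(classification = cls$classification, msl = cls$msl, amova = am,
         pairwise = pw, pcoa = pc, locusTests = lt,
         significantLoci = sig)
}

#' Run the relative gene-expression analysis
#'
#' Reads a long-format qPCR table (\code{sample,group,gene,cq,efficiency}),
#' normalizes against the configured reference genes and writes the
#' per-gene expression summary with fold changes, t statistics and q-values
#' computed jointly across the configured comparisons.
#'
#' @param config path to a YAML config, or a list; requires
#'   \code{qpcr_input}, \code{reference_genes} (2 labels) and
#'   \code{out_dir}; optional \code{qpcr_comparisons}, \code{confidence}.
#' @return Invisibly, the expression summary data.frame (also written to
#'   \code{out_dir/expression_summary.tsv}).
#' @export
runQpcrAnalysis <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    if (is.null(config$qpcr_input) || is.null(config$out_dir) ||
        is.null(config$reference_genes))
        stop("config must provide qpcr_input, reference_genes and out_dir")
    tab <- utils::read.csv(config$qpcr_input, stringsAsFactors = FALSE)
    refs <- unlist(config$reference_genes)
    missing <- setdiff(refs, tab$gene)
    if (length(missing))
        stop("reference gene(s) absent from data: ",
             paste(missing, collapse = ", "))
    qe <- new("QpcrExperiment",
              measurements = tab[, c("sample", "group", "gene", "cq",
                                     "efficiency")],
              referenceGenes = refs)
    validObject(qe)
    dcq <- deltaCq(qe)
    cmp <- config$qpcr_comparisons
    if (!is.null(cmp))
        cmp <- lapply(cmp, unlist)
    summary <- expressionTests(dcq, comparisons = cmp,
                               confidence = config$confidence)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(summary, file.path(config$out_dir, "expression_summary.tsv"))
    log <- file.path(config$out_dir, "qpcr_run.log")
    cat("msapDiff ", as.character(utils::packageVersion("msapDiff")),
        " qPCR analysis\nconfidence=", config$confidence, "\n",
        sep = "", file = log)
    invisible(summary)
}
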