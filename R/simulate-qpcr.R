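#' Configuration for the qPCR simulator
#'
#' Defines a relative-quantification experiment: target genes with known true
#' log2 fold changes between a control group and treatment groups, two stable
#' reference genes (true fold change 0 by construction), per-gene baseline Cq
#' and amplification efficiency, and Gaussian cycle noise.  Defaults mirror a
#' two-group design with n = 4 biological replicates per group.
#'
#' @param genes character vector of target gene labels.
#' @param referenceGenes exactly two reference gene labels (appended to the
#'   gene set if not already present).
#' @param groups group labels; the first is the control.
#' @param nReplicates replicates per group (>= 2).
#' @param trueLog2fc named numeric of true log2 fold changes
#'   (treatment vs control) per target gene; unnamed scalar recycled.
#'   Reference genes always have true fold change 0; supplying a non-zero
#'   value for a reference gene is an error.
#' @param baseCq named numeric (or scalar) baseline Cq in cycles per gene.
#' @param efficiencies named numeric (or scalar) amplification efficiency E in
#'   (0, 1] per gene.
#' @param noiseSd Gaussian Cq noise standard deviation in cycles (>= 0).
#' @param seed integer seed.
#' @return A validated list of class \code{"QpcrSimConfig"}.
#' @export
qpcrSimConfig <- function(genes = c("tgt1", "tgt2"),
                          referenceGenes = c("ref1", "ref2"),
                          groups = c("control", "treatment"),
                          nReplicates = 4L, trueLog2fc = 1,
                          baseCq = 24, efficiencies = 1,
                          noiseSd = 0.3, seed = 1L) {
    if (length(referenceGenes) != 2L || anyDuplicated(referenceGenes))
        stop("exactly 2 distinct reference genes are required")
    genes <- as.character(genes)
    allGenes <- union(genes, referenceGenes)
    targets <- setdiff(allGenes, referenceGenes)
    if (!length(targets))
        stop("at least one target gene is required")
    if (length(groups) < 2L || anyDuplicated(groups))
        stop("at least 2 distinct groups are required")
    nReplicates <- as.integer(nReplicates)
    if (is.na(nReplicates) || nReplicates < 2L)
        stop("'nReplicates' must be >= 2")
    expand <- function(x, what, who) {
        if (is.null(names(x))) {
            if (length(x) == 1L)
                x <- stats::setNames(rep(x, length(who)), who)
            else if (length(x) == length(who))
                names(x) <- who
            else stop(sprintf("'%s' must be named or scalar", what))
        }
        miss <- setdiff(who, names(x))
        if (length(miss))
            stop(sprintf("'%s' missing for gene(s): %s", what,
                         paste(miss, collapse = ", ")))
        x[who]
    }
    if (!is.null(names(trueLog2fc))) {
        refLfc <- trueLog2fc[names(trueLog2fc) %in% referenceGenes]
        if (any(refLfc != 0))
            stop("reference genes must have true log2 fold change 0")
        trueLog2fc <- trueLog2fc[!names(trueLog2fc) %in% referenceGenes]
    }
    lfc <- expand(trueLog2fc, "trueLog2fc", targets)
    lfc <- c(lfc, stats::setNames(rep(0, 2L), referenceGenes))[allGenes]
    baseCq <- expand(baseCq, "baseCq", allGenes)
    eff <- expand(efficiencies, "efficiencies", allGenes)
    if (any(eff <= 0 | eff > 1))
        stop("'efficiencies' must lie in (0, 1]")
    if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
        stop("'noiseSd' must be a single value >= 0")
    structure(list(genes = allGenes, targets = targets,
                   referenceGenes = as.character(referenceGenes),
                   groups = as.character(groups), nReplicates = nReplicates,
                   trueLog2fc = lfc, baseCq = baseCq, efficiencies = eff,
                   noiseSd = noiseSd, seed = as.integer(seed)),
              class = "QpcrSimConfig")
}

#' Simulate a qPCR experiment with known fold changes
#'
#' Cq values are generated on the efficiency-corrected (base-2) scale as
#' \code{baseCq - trueLog2fc} (for treatment groups) plus Gaussian noise, and
#' divided by \code{log2(1 + E)} to give the instrument-scale Cq, so that
#' downstream efficiency correction recovers the configured fold changes at
#' every efficiency (for E = 1 the two scales coincide).
#'
#' @param config a [qpcrSimConfig()] object.
#' @return A list with \code{experiment} (a [QpcrExperiment-class]) and
#'   \code{truth} (named true log2 fold changes per gene plus the config).
#' @examples
#' sim <- simulateQpcr(qpcrSimConfig(noiseSd = 0, seed = 3))
#' head(measurements(sim$experiment))
#' @export
simulateQpcr <- function(config) {
    if (!inherits(config, "QpcrSimConfig"))
        config <- do.call(qpcrSimConfig, as.list(config))
    withSeed(config$seed, {
        grid <- expand.grid(rep = seq_len(config$nReplicates),
                            group = config$groups, gene = config$genes,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        treat <- grid$group != config$groups[1L]
        ideal <- config$baseCq[grid$gene] -
            config$trueLog2fc[grid$gene] * treat +
            stats::rnorm(nrow(grid), 0, config$noiseSd)
        eff <- config$efficiencies[grid$gene]
        df <- data.frame(sample = sprintf("%s_r%d", grid$group, grid$rep),
                         group = grid$group, gene = grid$gene,
                         cq = as.numeric(ideal / log2(1 + eff)),
                         efficiency = as.numeric(eff),
                         stringsAsFactors = FALSE)
        exp <- new("QpcrExperiment", measurements = df,
                   referenceGenes = config$referenceGenes)
        validObject(exp)
        list(experiment = exp,
             truth = list(trueLog2fc = config$trueLog2fc, config = config))
    })
}
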