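#' Configuration for the MSAP simulator
#'
#' Defines the statistical structure of a simulated MSAP study: groups of
#' samples typed at a set of anonymous loci, each locus carrying a probability
#' vector over the four methylation types (I unmethylated, II internal
#' cytosine methylation, III hemi-methylated, IV hypermethylated), a fraction
#' of loci truly differentiated between groups, per-band scoring error and
#' missing calls.  Defaults mirror a three-group larval design (group sizes
#' 21/15/12, ~300 loci) with a modest differentiated fraction, per-band error
#' of 2\% and 2\% missing calls.
#'
#' @param groupSizes integer vector of samples per group (>= 2 in total).
#' @param nLoci number of loci.
#' @param baselineStateProbs baseline per-locus probabilities over types
#'   I--IV: a length-4 vector (recycled over loci), an nLoci x 4 matrix, or a
#'   function \code{f(nLoci)} returning such a matrix.  Default: a Dirichlet
#'   sampler with shape (5, 2, 1.5, 1.5), i.e. on average half the bands
#'   unmethylated.
#' @param diffFraction fraction in [0, 1] of loci whose state probabilities
#'   differ between groups.
#' @param effectSize total-variation shift in [0, 1] applied at differentiated
#'   loci in non-reference groups (probability mass moved from type I toward
#'   types II/III/IV proportionally to their baseline mass).
#' @param errorRate per-band probability of flipping a presence call.
#' @param missingRate per-band probability of a missing call.
#' @param groupNames optional group labels (default G1, G2, ...).
#' @param seed integer seed; the simulation is a deterministic function of it.
#' @return A validated list of class \code{"MsapSimConfig"}.
#' @seealso [simulateMsap()]
#' @export
msapSimConfig <- function(groupSizes = c(21L, 15L, 12L), nLoci = 300L,
                          baselineStateProbs = NULL, diffFraction = 0.2,
                          effectSize = 0.4, errorRate = 0.02,
                          missingRate = 0.02, groupNames = NULL, seed = 1L) {
    groupSizes <- as.integer(groupSizes)
    if (length(groupSizes) < 1L || any(is.na(groupSizes) | groupSizes < 1L))
        stop("'groupSizes' must be positive integers")
    if (sum(groupSizes) < 2L)
        stop("'groupSizes' must sum to at least 2")
    nLoci <- as.integer(nLoci)
    if (is.na(nLoci) || nLoci < 1L)
        stop("'nLoci' must be a positive integer")
    .checkFraction(diffFraction, "diffFraction")
    .checkFraction(effectSize, "effectSize")
    .checkFraction(errorRate, "errorRate")
    .checkFraction(missingRate, "missingRate")
    if (is.null(groupNames))
        groupNames <- sprintf("G%d", seq_along(groupSizes))
    if (length(groupNames) != length(groupSizes))
        stop("'groupNames' must match 'groupSizes' in length")
    if (!is.null(baselineStateProbs) && !is.function(baselineStateProbs)) {
        if (is.numeric(baselineStateProbs) &&
            length(baselineStateProbs) == 4L)
            baselineStateProbs <- matrix(baselineStateProbs, nLoci, 4L,
                                         byrow = TRUE)
        baselineStateProbs <- as.matrix(baselineStateProbs)
        if (!identical(dim(baselineStateProbs), c(nLoci, 4L)))
            stop("'baselineStateProbs' must be a 4-vector or an nLoci x 4 ",
                 "matrix")
        if (any(baselineStateProbs < 0) ||
            any(abs(rowSums(baselineStateProbs) - 1) > 1e-12))
            stop("'baselineStateProbs' rows must be probability vectors ",
                 "summing to 1")
    }
    structure(list(groupSizes = groupSizes, nLoci = nLoci,
                   baselineStateProbs = baselineStateProbs,
                   diffFraction = diffFraction, effectSize = effectSize,
                   errorRate = errorRate, missingRate = missingRate,
                   groupNames = as.character(groupNames),
                   seed = as.integer(seed)),
              class = "MsapSimConfig")
}

# Dirichlet draw via independent gammas.
.rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                n, length(alpha))
    g / rowSums(g)
}

# Map methylation type codes 1..4 to the (HpaII, MspI) band-presence pattern:
# I -> (1,1), II -> (0,1), III -> (1,0), IV -> (0,0).
.typeToHpa <- c(1L, 0L, 1L, 0L)
.typeToMsp <- c(1L, 1L, 0L, 0L)

#' Simulate an MSAP band-call dataset with known ground truth
#'
#' Draws, per sample, a methylation type at each locus from its group's
#' state-probability vector, maps the type to the two-enzyme presence pattern
#' (type I: both bands; II: MspI only; III: HpaII only; IV: neither), then
#' corrupts each band call independently with flip errors at
#' \code{errorRate} and masks it as missing at \code{missingRate}.  The
#' reference (first) group keeps the baseline probabilities; at differentiated
#' loci the other groups have \code{effectSize} probability mass moved from
#' type I toward types II/III/IV proportionally, emulating temperature-driven
#' shifts between methylation states.
#'
#' @param config a [msapSimConfig()] object.
#' @return A list with elements \code{experiment} (a
#'   [MsapExperiment-class]), and \code{truth}: a list with
#'   \code{differentiatedLoci} (locus ids), \code{states} (the true loci x
#'   samples type matrix before corruption), \code{stateProbs} (loci x 4 x
#'   groups array) and the \code{config}.
#' @examples
#' sim <- simulateMsap(msapSimConfig(groupSizes = c(5, 5), nLoci = 40,
#'                                   seed = 7))
#' sim$experiment
#' @export
simulateMsap <- function(config) {
    if (!inherits(config, "MsapSimConfig"))
        config <- do.call(msapSimConfig, as.list(config))
    withSeed(config$seed, {
        L <- config$nLoci
        G <- length(config$groupSizes)
        N <- sum(config$groupSizes)
        base <- config$baselineStateProbs
        if (is.null(base))
            base <- .rdirichlet(L, c(5, 2, 1.5, 1.5))
        else if (is.function(base)) {
            base <- as.matrix(base(L))
            if (!identical(dim(base), c(L, 4L)) ||
                any(abs(rowSums(base) - 1) > 1e-12))
                stop("baseline sampler must return an nLoci x 4 probability ",
                     "matrix")
        }
        k <- round(config$diffFraction * L)
        diffLoci <- sort(sample.int(L, k))

        probs <- array(rep(base, G), dim = c(L, 4L, G))
        if (k && G > 1L && config$effectSize > 0) {
            shifted <- base[diffLoci, , drop = FALSE]
            delta <- pmin(config$effectSize, shifted[, 1L])
            rest <- shifted[, 2:4, drop = FALSE]
            w <- rest / ifelse(rowSums(rest) > 0, rowSums(rest), 1)
            w[rowSums(rest) == 0, ] <- 1 / 3
            shifted[, 1L] <- shifted[, 1L] - delta
            shifted[, 2:4] <- rest + delta * w
            for (g in 2:G)
                probs[diffLoci, , g] <- shifted
        }

        groupOf <- rep(seq_len(G), config$groupSizes)
        states <- matrix(0L, L, N)
        for (g in seq_len(G)) {
            cols <- which(groupOf == g)
            cum <- t(apply(probs[, , g, drop = FALSE], 1L, cumsum))
            u <- matrix(stats::runif(L * length(cols)), L)
            states[, cols] <- 1L + (u > cum[, 1L]) + (u > cum[, 2L]) +
                (u > cum[, 3L])
        }

        hpa <- matrix(.typeToHpa[states], L, N)
        msp <- matrix(.typeToMsp[states], L, N)
        if (config$errorRate > 0) {
            flip <- function(m) {
                f <- matrix(stats::runif(length(m)) < config$errorRate,
                            nrow(m))
                m[f] <- 1L - m[f]
                m
            }
            hpa <- flip(hpa)
            msp <- flip(msp)
        }
        if (config$missingRate > 0) {
            hpa[matrix(stats::runif(length(hpa)) < config$missingRate,
                       L)] <- NA_integer_
            msp[matrix(stats::runif(length(msp)) < config$missingRate,
                       L)] <- NA_integer_
        }

        locusIds <- sprintf("L%04d", seq_len(L))
        sampleIds <- sprintf("%s_S%02d", config$groupNames[groupOf],
                             unlist(lapply(config$groupSizes, seq_len)))
        dimnames(hpa) <- dimnames(msp) <- list(locusIds, sampleIds)
        dimnames(states) <- list(locusIds, sampleIds)
        dimnames(probs) <- list(locusIds, c("I", "II", "III", "IV"),
                                config$groupNames)
        exp <- MsapExperiment(hpa, msp,
                              group = config$groupNames[groupOf])
        list(experiment = exp,
             truth = list(differentiatedLoci = locusIds[diffLoci],
                          states = states, stateProbs = probs,
                          config = config))
    })
}

#' Write simulation ground truth as a tab-separated sidecar table
#'
#' One row per locus with a flag marking truly differentiated loci and the
#' per-group type-I probability (a compact summary of the state shift).
#'
#' @param truth the \code{truth} element returned by [simulateMsap()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
    p1 <- truth$stateProbs[, 1L, , drop = FALSE]
    df <- data.frame(locus = rownames(truth$stateProbs),
                     differentiated = rownames(truth$stateProbs) %in%
                         truth$differentiatedLoci,
                     stringsAsFactors = FALSE)
    for (g in dimnames(truth$stateProbs)[[3L]])
        df[[paste0("p_typeI_", g)]] <- p1[, 1L, g]
    writeTsv(df, path)
}
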