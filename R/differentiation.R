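#' Squared pairwise distances between methylation profiles
#'
#' For samples i, j the squared distance is the number of loci with opposite
#' binary states, rescaled for missing data:
#' \deqn{d^2_{ij} = (L / L_{ij}) \times m_{ij}}
#' where L is the total locus count, \eqn{L_{ij}} the loci non-missing in
#' both samples and \eqn{m_{ij}} the mismatches among them.  With complete
#' data this is the squared Euclidean distance on 0/1 vectors, the standard
#' convention for AMOVA on binary (dominant) markers.
#'
#' @param x a [MslBinaryMatrix-class] object, or a plain loci x samples
#'   0/1/NA matrix.
#' @return Samples x samples symmetric numeric matrix of squared distances
#'   (zero diagonal).
#' @export
msapDistance <- function(x) {
    m <- if (is(x, "MslBinaryMatrix")) mslStates(x) else as.matrix(x)
    if (ncol(m) < 2L)
        stop("at least 2 samples are required")
    L <- nrow(m)
    one <- (m == 1L) & !is.na(m)
    zero <- (m == 0L) & !is.na(m)
    obs <- !is.na(m)
    mism <- crossprod(one, zero)
    mism <- mism + t(mism)
    lij <- crossprod(obs * 1)
    bad <- which(lij == 0 & upper.tri(lij), arr.ind = TRUE)
    if (nrow(bad))
        stop("sample pair(s) share no non-missing locus: ",
             paste(sprintf("%s/%s", colnames(m)[bad[, 1L]],
                           colnames(m)[bad[, 2L]]), collapse = ", "))
    d2 <- L * mism / lij
    diag(d2) <- 0
    dimnames(d2) <- list(colnames(m), colnames(m))
    d2
}

#' AMOVA variance components from sums of squares
#'
#' Single-level analysis of molecular variance: given the among- and
#' within-group sums of square deviations and the group sizes, computes mean
#' squares (MSD = SSD/df), the weighted average group size
#' \eqn{n_0 = (N - \sum n_g^2 / N) / (G - 1)}, the variance components
#' \eqn{\sigma^2_{within} = MSD_{within}} and
#' \eqn{\sigma^2_{among} = (MSD_{among} - MSD_{within}) / n_0} (negative
#' components are retained, not truncated), and
#' \eqn{\Phi_{ST} = \sigma^2_{among} / (\sigma^2_{among} +
#' \sigma^2_{within})}.
#'
#' @param ssdAmong,ssdWithin sums of square deviations.
#' @param groupSizes integer vector of group sizes (G >= 2, N >= G + 1).
#' @return An [AmovaResult-class] without permutation fields.
#' @examples
#' varianceComponents(238.6, 1335.0, c(21, 15, 12))
#' @export
varianceComponents <- function(ssdAmong, ssdWithin, groupSizes) {
    groupSizes <- as.integer(groupSizes)
    G <- length(groupSizes)
    N <- sum(groupSizes)
    if (G < 2L || any(groupSizes < 1L))
        stop("need >= 2 groups, each of size >= 1")
    if (N < G + 1L)
        stop("need N >= G + 1 for a within-group degree of freedom")
    df <- c(among = G - 1L, within = N - G, total = N - 1L)
    msd <- c(among = ssdAmong / df[["among"]],
             within = ssdWithin / df[["within"]])
    n0 <- (N - sum(groupSizes^2) / N) / (G - 1L)
    s2w <- msd[["within"]]
    s2a <- (msd[["among"]] - s2w) / n0
    if (s2a + s2w == 0)
        stop("Phi_ST undefined: total variance is zero")
    if (is.null(names(groupSizes)))
        names(groupSizes) <- sprintf("g%d", seq_len(G))
    new("AmovaResult", df = df,
        ssd = c(among = ssdAmong, within = ssdWithin,
                total = ssdAmong + ssdWithin),
        msd = msd, n0 = n0,
        sigma2 = c(among = unname(s2a), within = unname(s2w)),
        phiST = unname(s2a / (s2a + s2w)),
        nPermutations = 0L, pPerm = NA_real_, groupSizes = groupSizes)
}

# Within-group SSD for a squared-distance matrix under a group assignment
# (integer codes 1..G): sum over groups of (sum of within-group pair d2)/n_g.
.ssdWithin <- function(d2, code, G) {
    s <- 0
    for (g in seq_len(G)) {
        idx <- which(code == g)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
}

#' AMOVA with permutation test on Phi_ST
#'
#' Partitions the total squared-deviation sum,
#' \eqn{SSD_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}}, into within-group
#' (\eqn{\sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}}) and among-group
#' parts, derives variance components via [varianceComponents()], and tests
#' differentiation by shuffling the sample-to-group assignment (preserving
#' group sizes).  The p-value uses the (1 + b)/(1 + B) estimator, so it can
#' never be exactly zero; report p < 1/B when no permuted \eqn{\Phi_{ST}}
#' reaches the observed one.
#'
#' @param d2 symmetric samples x samples matrix of squared distances
#'   (from [msapDistance()]).
#' @param groups per-sample group labels (>= 2 groups, each non-empty).
#' @param nPermutations number of label permutations (0 skips the test;
#'   default 10000; raise to 1e6 for publication-grade resolution).
#' @param seed integer seed for the permutation stream.
#' @return An [AmovaResult-class].
#' @export
amova <- function(d2, groups, nPermutations = 10000L, seed = 1L) {
    d2 <- as.matrix(d2)
    N <- nrow(d2)
    groups <- as.character(groups)
    if (length(groups) != N)
        stop("'groups' must have one label per sample")
    sizes <- table(groups)
    if (length(sizes) < 2L)
        stop("need >= 2 groups")
    if (any(sizes == 0L))
        stop("every group needs at least one sample")
    lv <- names(sizes)
    code <- match(groups, lv)
    G <- length(lv)
    ssdTotal <- sum(d2) / (2 * N)
    ssdWithin <- .ssdWithin(d2, code, G)
    ssdAmong <- ssdTotal - ssdWithin
    res <- varianceComponents(ssdAmong, ssdWithin,
                              stats::setNames(as.integer(sizes), lv))
    nPermutations <- as.integer(nPermutations)
    if (nPermutations > 0L) {
        obs <- res@phiST
        dfA <- G - 1L
        dfW <- N - G
        n0 <- res@n0
        # count ties as exceedances: summation order differs between
        # permutations, so equality is tested with a small relative tolerance
        tol <- 1e-10 * (1 + abs(obs))
        exceed <- withSeed(seed, {
            cnt <- 0L
            for (b in seq_len(nPermutations)) {
                pw <- .ssdWithin(d2, sample(code), G)
                msdA <- (ssdTotal - pw) / dfA
                msdW <- pw / dfW
                s2a <- (msdA - msdW) / n0
                phi <- s2a / (s2a + msdW)
                if (!is.nan(phi) && phi >= obs - tol)
                    cnt <- cnt + 1L
            }
            cnt
        })
        res@nPermutations <- nPermutations
        res@pPerm <- (1 + exceed) / (1 + nPermutations)
    }
    res
}

#' Pairwise-group AMOVA
#'
#' One AMOVA per unordered pair of groups, restricted to that pair's samples.
#' P-values are reported raw (no multiplicity adjustment).
#'
#' @inheritParams amova
#' @return A data.frame with one row per pair (columns: group1, group2,
#'   phi_st, sigma2_among, sigma2_within, p_perm) and the full
#'   [AmovaResult-class] objects as attribute \code{"results"}.
#' @export
pairwiseGroupAmova <- function(d2, groups, nPermutations = 10000L,
                               seed = 1L) {
    d2 <- as.matrix(d2)
    groups <- as.character(groups)
    lv <- sort(unique(groups))
    if (length(lv) < 2L)
        stop("need >= 2 groups")
    combos <- utils::combn(lv, 2L)
    rows <- vector("list", ncol(combos))
    results <- vector("list", ncol(combos))
    for (i in seq_len(ncol(combos))) {
        pair <- combos[, i]
        sel <- groups %in% pair
        r <- amova(d2[sel, sel, drop = FALSE], groups[sel], nPermutations,
                   seed = deriveSeed(seed, paste(pair, collapse = "|")))
        results[[i]] <- r
        rows[[i]] <- data.frame(group1 = pair[1L], group2 = pair[2L],
                                phi_st = r@phiST,
                                sigma2_among = r@sigma2[["among"]],
                                sigma2_within = r@sigma2[["within"]],
                                p_perm = r@pPerm,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "results") <- results
    out
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Classical (Torgerson) metric scaling: double-center \eqn{-d^2/2},
#' eigendecompose, and scale eigenvectors by the square root of their
#' (positive) eigenvalues.  Axes are ordered by decreasing eigenvalue;
#' negative-eigenvalue axes are dropped with a message, and the percentage of
#' variance per retained axis is computed over positive eigenvalues only.
#'
#' @param d2 symmetric samples x samples matrix of squared distances.
#' @return A [PcoaResult-class].
#' @export
runPcoa <- function(d2) {
    d2 <- as.matrix(d2)
    if (nrow(d2) < 2L)
        stop("at least 2 samples are required")
    # axis selection (positive eigenvalues) is handled below
    sc <- suppressWarnings(stats::cmdscale(sqrt(d2), k = nrow(d2) - 1L,
                                           eig = TRUE))
    eig <- sc$eig
    tol <- max(abs(eig)) * 1e-9
    pos <- which(eig > tol)
    if (any(eig < -tol))
        message(sum(eig < -tol),
                " negative eigenvalue(s) dropped (non-Euclidean distances)")
    coords <- sc$points[, seq_along(pos), drop = FALSE]
    colnames(coords) <- sprintf("Axis%d", seq_along(pos))
    rownames(coords) <- rownames(d2)
    new("PcoaResult", coordinates = coords, eigenvalues = eig,
        pctVariance = 100 * eig[pos] / sum(eig[pos]))
}

#' Export an AMOVA result as a tab-separated table
#'
#' Columns follow the conventional AMOVA report layout: source of variation,
#' degrees of freedom, SSD, MSD, variance component, Phi_ST and permutation
#' p-value.
#'
#' @param x an [AmovaResult-class] object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAmovaTable <- function(x, path) {
    stopifnot(is(x, "AmovaResult"))
    df <- data.frame(
        source = c("Among groups", "Within groups", "Total"),
        df = as.integer(x@df),
        SSD = as.numeric(x@ssd),
        MSD = c(x@msd, NA_real_),
        variance = c(x@sigma2, NA_real_),
        phi_st = c(x@phiST, NA_real_, NA_real_),
        p = c(x@pPerm, NA_real_, NA_real_),
        stringsAsFactors = FALSE)
    writeTsv(df, path)
}
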