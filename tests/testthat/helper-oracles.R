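## Independent brute-force oracles used across the suite.  These are written
## from the definitions, not by calling package internals.

# Squared mismatch distance with missing-data rescaling, one pair at a time.
oracleDist <- function(states) {
    n <- ncol(states)
    L <- nrow(states)
    d2 <- matrix(0, n, n, dimnames = list(colnames(states),
                                          colnames(states)))
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            ok <- !is.na(states[, i]) & !is.na(states[, j])
            d2[i, j] <- L / sum(ok) * sum(states[ok, i] != states[ok, j])
        }
    }
    d2
}

# AMOVA from first principles: explicit loops over sample pairs.
oracleAmova <- function(d2, groups) {
    n <- nrow(d2)
    lv <- unique(groups)
    ssdT <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) ssdT <- ssdT + d2[i, j]
    ssdT <- ssdT / n
    ssdW <- 0
    for (g in lv) {
        idx <- which(groups == g)
        s <- 0
        if (length(idx) > 1)
            for (a in seq_along(idx)[-length(idx)])
                for (b in (a + 1):length(idx))
                    s <- s + d2[idx[a], idx[b]]
        ssdW <- ssdW + s / length(idx)
    }
    ssdA <- ssdT - ssdW
    G <- length(lv)
    sizes <- as.integer(table(groups)[lv])
    msdA <- ssdA / (G - 1)
    msdW <- ssdW / (n - G)
    n0 <- (n - sum(sizes^2) / n) / (G - 1)
    s2a <- (msdA - msdW) / n0
    phi <- s2a / (s2a + msdW)
    list(ssdTotal = ssdT, ssdWithin = ssdW, ssdAmong = ssdA,
         msdAmong = msdA, msdWithin = msdW, n0 = n0, sigma2Among = s2a,
         sigma2Within = msdW, phi = phi)
}

# Exhaustive permutation null: every distinct assignment of samples to
# groups with the observed group sizes, each counted once.
oracleExactPerm <- function(d2, groups) {
    n <- nrow(d2)
    lv <- unique(groups)
    sizes <- as.integer(table(groups)[lv])
    assignments <- list()
    build <- function(remaining, assigned) {
        gnext <- length(assigned) + 1L
        if (gnext > length(lv)) {
            assignments[[length(assignments) + 1L]] <<- assigned
            return(invisible())
        }
        if (gnext == length(lv)) {
            build(integer(0), c(assigned, list(remaining)))
            return(invisible())
        }
        picks <- combn(remaining, sizes[gnext], simplify = FALSE)
        for (p in picks)
            build(setdiff(remaining, p), c(assigned, list(p)))
    }
    build(seq_len(n), list())
    phis <- vapply(assignments, function(a) {
        lab <- character(n)
        for (g in seq_along(a)) lab[a[[g]]] <- lv[g]
        oracleAmova(d2, lab)$phi
    }, 0)
    phis
}

# Two-sided Fisher exact p for a 2 x 2 table by hypergeometric enumeration.
oracleFisher22 <- function(tab) {
    m <- sum(tab[1, ])
    n <- sum(tab[2, ])
    k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided Fisher exact p for a 2 x 3 table by full enumeration over the
# two free cells, margins fixed.
oracleFisher23 <- function(tab) {
    rs <- rowSums(tab)
    cs <- colSums(tab)
    N <- sum(tab)
    logProb <- function(t)
        sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
            sum(lfactorial(t))
    obs <- logProb(tab)
    total <- 0
    for (a in 0:min(rs[1], cs[1])) {
        for (b in 0:min(rs[1] - a, cs[2])) {
            cc <- rs[1] - a - b
            if (cc > cs[3]) next
            t2 <- cs - c(a, b, cc)
            if (any(t2 < 0)) next
            t <- rbind(c(a, b, cc), t2)
            lp <- logProb(t)
            if (lp <= obs + 1e-7)
                total <- total + exp(lp)
        }
    }
    total
}

# Naive O(n^3) UPGMA: recompute every cluster pair's mean leaf-pair distance
# from the original matrix at each step.
oracleUpgma <- function(d) {
    labels <- rownames(d)
    clusters <- lapply(seq_len(nrow(d)), identity)
    reps <- labels
    merges <- list()
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- NULL
        bestD <- Inf
        bestKey <- NULL
        for (i in seq_along(clusters)[-length(clusters)]) {
            for (j in (i + 1):length(clusters)) {
                dd <- mean(d[clusters[[i]], clusters[[j]]])
                key <- sort(c(reps[i], reps[j]))
                take <- dd < bestD - 1e-12 ||
                    (abs(dd - bestD) <= 1e-12 &&
                     (key[1] < bestKey[1] ||
                      (key[1] == bestKey[1] && key[2] < bestKey[2])))
                if (take) {
                    best <- c(i, j)
                    bestD <- dd
                    bestKey <- key
                }
            }
        }
        i <- best[1]; j <- best[2]
        merges[[length(merges) + 1L]] <-
            sort(labels[c(clusters[[i]], clusters[[j]])])
        heights <- c(heights, bestD)
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        reps[i] <- min(reps[i], reps[j])
        clusters[[j]] <- NULL
        reps <- reps[-j]
    }
    list(merges = merges, heights = heights)
}

# Leaf membership of each internal node of an hclust-style merge matrix,
# as sorted label sets, in merge order.
mergeSets <- function(tree) {
    out <- vector("list", nrow(tree$merge))
    rec <- function(node) {
        if (node < 0) return(tree$labels[-node])
        out[[node]]
    }
    for (s in seq_len(nrow(tree$merge))) {
        out[[s]] <- sort(c(rec(tree$merge[s, 1]), rec(tree$merge[s, 2])))
    }
    out
}

# Independently coded Storey q-values (smoother pi0), following the
# published estimator step by step.
oracleStorey <- function(p) {
    m <- length(p)
    lam <- seq(0.05, 0.95, 0.05)
    pi0Hat <- sapply(lam, function(l) sum(p > l) / (m * (1 - l)))
    spl <- smooth.spline(lam, pi0Hat, df = 3)
    pi0 <- predict(spl, x = 0.95)$y
    pi0 <- min(max(pi0, 1 / m), 1)
    ord <- order(p)
    ps <- p[ord]
    q <- pi0 * m * ps / seq_len(m)
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[ord] <- q
    out
}

# Tiny fixture builders -------------------------------------------------

makeMsap <- function(hpa, msp, group, ...) {
    L <- nrow(hpa)
    dimnames(hpa) <- dimnames(msp) <-
        list(sprintf("L%02d", seq_len(L)), sprintf("s%02d", seq_len(ncol(hpa))))
    MsapExperiment(hpa, msp, group = group, ...)
}

# MslBinaryMatrix straight from a 0/1/NA loci x samples matrix.
makeMsl <- function(states, group) {
    if (is.null(rownames(states)))
        dimnames(states) <- list(sprintf("L%02d", seq_len(nrow(states))),
                                 sprintf("s%02d", seq_len(ncol(states))))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(methylated = states),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(states)))
    new("MslBinaryMatrix", se)
}

makeCalls <- function(types, group) {
    if (is.null(rownames(types)))
        dimnames(types) <- list(sprintf("L%02d", seq_len(nrow(types))),
                                sprintf("s%02d", seq_len(ncol(types))))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(type = types),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(types)))
    new("MethylationCalls", se)
}

# Session-level cache so expensive stochastic studies run once per test run.
.simCache <- new.env(parent = emptyenv())

cachedNullStudy <- function() {
    if (!is.null(.simCache$null))
        return(.simCache$null)
    cfg0 <- msapSimConfig(groupSizes = c(8L, 8L, 8L), nLoci = 60L,
                          diffFraction = 0, errorRate = 0, missingRate = 0,
                          seed = 0L)
    pvals <- vapply(seq_len(500L), function(r) {
        cfg <- cfg0
        cfg$seed <- 1000L + r
        sim <- simulateMsap(cfg)
        cls <- classifyLoci(callMethylationTypes(sim$experiment))
        d2 <- msapDistance(cls$msl)
        amova(d2, sampleGroups(cls$msl), nPermutations = 999L,
              seed = r)@pPerm
    }, 0)
    .simCache$null <- pvals
    pvals
}
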