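test_that("squared distances count mismatches, rescaled for missing data", {
    st <- cbind(a = c(0L, 0L, 0L, 0L), b = c(1L, 1L, 1L, 1L),
                c = c(0L, 0L, 0L, 0L))
    rownames(st) <- sprintf("L%d", 1:4)
    d2 <- msapDistance(st)
    expect_equal(d2["a", "b"], 4)
    expect_equal(d2["a", "c"], 0)
    expect_equal(diag(d2), c(a = 0, b = 0, c = 0))

    # one missing cell, 1 mismatch among the 3 complete loci -> 4/3
    st2 <- cbind(a = c(NA, 0L, 0L, 0L), b = c(1L, 1L, 0L, 0L))
    expect_equal(msapDistance(st2)[1, 2], 4 / 3)

    # a pair sharing no locus is an error naming the pair
    st3 <- cbind(a = c(1L, NA), b = c(NA, 1L))
    colnames(st3) <- c("sampleA", "sampleB")
    expect_error(msapDistance(st3), "sampleA/sampleB")
    expect_error(msapDistance(st[, 1, drop = FALSE]), "2 samples")
})

test_that("distances agree with the per-pair oracle under missingness", {
    set.seed(4)
    st <- matrix(sample(c(0L, 1L, NA), 200, TRUE,
                        prob = c(0.45, 0.45, 0.1)), 20, 10)
    colnames(st) <- sprintf("s%02d", 1:10)
    expect_equal(msapDistance(st), oracleDist(st))
})

test_that("variance components implement the AMOVA estimators", {
    r <- varianceComponents(238.6, 1335.0, c(21, 15, 12))
    expect_identical(r@df, c(among = 2L, within = 45L, total = 47L))
    expect_equal(r@msd[["among"]], 119.3)
    expect_equal(r@n0, 15.5625)
    expect_equal(r@sigma2[["within"]], 1335 / 45)
    # equal mean squares partition nothing among groups
    r0 <- varianceComponents(10, 90, c(5, 5, 5))   # msd 5 vs 7.5
    rEq <- varianceComponents(2 * 7.5, 90, c(5, 5, 5))
    expect_equal(rEq@sigma2[["among"]], 0)
    expect_equal(rEq@phiST, 0)
    expect_lt(r0@phiST, 0)    # negative component retained, not truncated
    expect_error(varianceComponents(1, 1, c(5)), "2 groups")
    expect_error(varianceComponents(0, 0, c(2, 2)), "undefined")
    expect_error(varianceComponents(1, 1, c(1, 1)), "N >= G")
})

test_that("amova matches the exhaustive oracle on small instances", {
    set.seed(7)
    for (rep in 1:8) {
        N <- sample(4:8, 1)
        G <- sample(2:min(3, N - 1), 1)
        repeat {
            groups <- sort(sample(sprintf("g%d", 1:G), N, replace = TRUE))
            if (length(unique(groups)) == G && max(table(groups)) < N) break
        }
        st <- matrix(sample(c(0L, 1L), N * 12, TRUE), 12, N)
        colnames(st) <- sprintf("s%d", 1:N)
        d2 <- msapDistance(st)
        ora <- oracleAmova(d2, groups)
        if (ora$sigma2Among + ora$sigma2Within == 0) next
        res <- amova(d2, groups, nPermutations = 0L)
        expect_equal(res@ssd[["total"]], ora$ssdTotal)
        expect_equal(res@ssd[["within"]], ora$ssdWithin)
        expect_equal(res@msd[["among"]], ora$msdAmong)
        expect_equal(res@n0, ora$n0)
        expect_equal(res@sigma2[["among"]], ora$sigma2Among)
        expect_equal(res@phiST, ora$phi)
    }
})

test_that("the seeded permutation p converges to the exact enumeration", {
    set.seed(42)
    st <- matrix(sample(c(0L, 1L), 6 * 15, TRUE), 15, 6)
    colnames(st) <- sprintf("s%d", 1:6)
    groups <- rep(c("a", "b"), each = 3)
    d2 <- msapDistance(st)
    obs <- oracleAmova(d2, groups)$phi
    phis <- oracleExactPerm(d2, groups)
    expect_length(phis, choose(6, 3))
    pExact <- mean(phis >= obs - 1e-12)
    res <- amova(d2, groups, nPermutations = 20000L, seed = 3)
    # (1+b)/(1+B) estimator converges to the assignment-uniform exact p
    expect_lt(abs(res@pPerm - pExact),
              3 * sqrt(pExact * (1 - pExact) / 20000) + 1e-4)
})

test_that("identical profiles within distinct groups give Phi_ST = 1", {
    st <- cbind(a1 = c(0L, 0L, 1L), a2 = c(0L, 0L, 1L),
                b1 = c(1L, 1L, 0L), b2 = c(1L, 1L, 0L))
    d2 <- msapDistance(st)
    res <- amova(d2, c("A", "A", "B", "B"), nPermutations = 0L)
    expect_equal(res@ssd[["within"]], 0)
    expect_equal(res@phiST, 1)
})

test_that("Phi_ST is invariant to sample and locus reordering", {
    sim <- simulateMsap(msapSimConfig(groupSizes = c(6, 6), nLoci = 60,
                                      seed = 15))
    cls <- classifyLoci(callMethylationTypes(sim$experiment))
    st <- mslStates(cls$msl)
    grp <- sampleGroups(cls$msl)
    base <- amova(msapDistance(st), grp, nPermutations = 0L)@phiST
    set.seed(1)
    ps <- sample(ncol(st))
    pl <- sample(nrow(st))
    expect_equal(amova(msapDistance(st[pl, ps]), grp[ps],
                       nPermutations = 0L)@phiST, base)
})

test_that("group handling contracts hold", {
    st <- matrix(sample(c(0L, 1L), 40, TRUE), 10, 4)
    colnames(st) <- sprintf("s%d", 1:4)
    d2 <- msapDistance(st)
    expect_error(amova(d2, c("a", "a", "a", "a"), 0L), "2 groups")
    expect_error(amova(d2, c("a", "a", "a"), 0L), "one label per sample")
})

test_that("pairwise AMOVA equals per-subset runs and skips self-pairs", {
    sim <- simulateMsap(msapSimConfig(groupSizes = c(5, 5, 5), nLoci = 80,
                                      seed = 23))
    cls <- classifyLoci(callMethylationTypes(sim$experiment))
    d2 <- msapDistance(cls$msl)
    grp <- sampleGroups(cls$msl)
    pw <- pairwiseGroupAmova(d2, grp, nPermutations = 99L, seed = 5)
    expect_identical(nrow(pw), 3L)
    expect_true(all(pw$group1 != pw$group2))
    for (i in seq_len(nrow(pw))) {
        sel <- grp %in% c(pw$group1[i], pw$group2[i])
        manual <- amova(d2[sel, sel], grp[sel], nPermutations = 0L)
        expect_equal(pw$phi_st[i], manual@phiST)
        expect_equal(pw$sigma2_among[i], manual@sigma2[["among"]])
    }
    # two groups total: the single row equals the full-data run
    sel <- grp %in% c("G1", "G2")
    pw2 <- pairwiseGroupAmova(d2[sel, sel], grp[sel],
                              nPermutations = 0L, seed = 5)
    expect_identical(nrow(pw2), 1L)
    expect_equal(pw2$phi_st,
                 amova(d2[sel, sel], grp[sel], nPermutations = 0L)@phiST)
})

test_that("PCoA recovers forced-symmetry configurations", {
    # two samples at squared distance 4: one axis at +-1, 100% variance
    d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
    pc <- runPcoa(d2)
    expect_identical(ncol(pc@coordinates), 1L)
    expect_equal(sort(pc@coordinates[, 1]), c(-1, 1),
                 ignore_attr = TRUE)
    expect_equal(pc@pctVariance, 100)

    # three mutually equidistant samples: two equal eigenvalues, 50/50
    d2 <- matrix(1, 3, 3) - diag(3)
    pc3 <- runPcoa(d2)
    eig <- pc3@eigenvalues
    pos <- eig[eig > 1e-9]
    expect_length(pos, 2L)
    expect_equal(pos[1], pos[2])
    expect_equal(pc3@pctVariance, c(50, 50))
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
    set.seed(12)
    pts <- matrix(rnorm(8 * 3), 8, 3)
    d2 <- as.matrix(dist(pts))^2
    dimnames(d2) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
    pc <- runPcoa(d2)
    rec <- as.matrix(dist(pc@coordinates))^2
    expect_lt(max(abs(rec - d2)), 1e-8)
    expect_equal(sum(pc@pctVariance), 100, tolerance = 1e-6)
})
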