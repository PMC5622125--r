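test_that("efficiency correction rescales Cq to the base-2 scale", {
    expect_equal(efficiencyCorrect(20, 1), 20)
    expect_equal(efficiencyCorrect(20, 0.9), 20 * log(1.9) / log(2))
    expect_equal(efficiencyCorrect(20, 0.9), 18.51999, tolerance = 1e-6)
    expect_error(efficiencyCorrect(20, 0), "\\(0, 1\\]")
    expect_error(efficiencyCorrect(20, 1.1), "\\(0, 1\\]")
})

qpcrFixture <- function(cqs, genes = names(cqs), eff = 1) {
    df <- data.frame(sample = "s1", group = "g", gene = genes,
                     cq = as.numeric(cqs), efficiency = eff,
                     stringsAsFactors = FALSE)
    new("QpcrExperiment", measurements = df,
        referenceGenes = c("ref1", "ref2"))
}

test_that("dCq normalizes against the reference mean", {
    x <- qpcrFixture(c(ref1 = 20, ref2 = 22, tgt = 25))
    expect_equal(deltaCq(x)$dcq, 4)
    # target equal to the reference mean -> 0
    x0 <- qpcrFixture(c(ref1 = 20, ref2 = 22, tgt = 21))
    expect_equal(deltaCq(x0)$dcq, 0)
    # permuting the references leaves dCq unchanged
    xp <- qpcrFixture(c(ref2 = 22, ref1 = 20, tgt = 25),
                      genes = c("ref2", "ref1", "tgt"))
    expect_equal(deltaCq(xp)$dcq, 4)
    # a sample lacking a reference Cq is rejected by the container
    bad <- data.frame(sample = c("s1", "s1", "s2"), group = "g",
                      gene = c("ref1", "ref2", "tgt"), cq = 20,
                      efficiency = 1)
    expect_error(new("QpcrExperiment", measurements = bad,
                     referenceGenes = c("ref1", "ref2")), "reference")
})

test_that("fold change propagates group errors in quadrature", {
    fc <- foldChange(c(4, 4, 4), c(5, 5, 5))
    expect_equal(fc$ddcq, -1)
    expect_equal(fc$log2fc, 1)
    expect_equal(fc$fold_change, 2)
    expect_equal(fc$fold_change, 2^fc$log2fc, tolerance = 1e-12)

    fc0 <- foldChange(c(3, 5), c(4, 4))
    expect_equal(fc0$log2fc, 0)
    expect_equal(fc0$fold_change, 1)

    # group SEs 0.3 and 0.4 combine in quadrature to 0.5
    tr <- c(-0.3, 0.3)                      # n = 2, sd 0.3*sqrt(2), SE 0.3
    expect_equal(sqrt(var(tr) / 2), 0.3)
    ct <- c(-0.4, 0.4)
    expect_equal(sqrt(var(ct) / 2), 0.4)
    fse <- foldChange(tr, ct)
    expect_equal(fse$se, 0.5)
    dfWS <- (0.09 + 0.16)^2 / (0.09^2 + 0.16^2)
    expect_equal(fse$df_se, dfWS)
    expect_equal(fse$ci_hi - fse$log2fc, qt(0.975, dfWS) * 0.5)

    # antisymmetry under swapping treatment and control
    set.seed(3)
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(foldChange(a, b)$log2fc, -foldChange(b, a)$log2fc)
    expect_error(foldChange(1, c(1, 2)), ">= 2")
})

test_that("expression t tests equal the pooled-variance formula", {
    xt <- c(3.1, 2.8, 3.4, 3.0)
    xc <- c(4.0, 4.3, 3.9, 4.4)
    dcq <- data.frame(sample = sprintf("s%d", 1:8),
                      group = rep(c("treat", "ctrl"), each = 4),
                      gene = "g1", dcq = c(xt, xc))
    res <- expressionTests(dcq, comparisons = list(c("treat", "ctrl")))
    sp2 <- (3 * var(xt) + 3 * var(xc)) / 6
    tHand <- (mean(xt) - mean(xc)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    expect_equal(res$t, tHand)
    expect_equal(res$df, 6)
    expect_equal(res$p, 2 * pt(-abs(tHand), 6))
    expect_equal(res$log2fc, -(mean(xt) - mean(xc)))
    expect_true(all(c("shapiro_p_treatment", "levene_p", "q") %in%
                    colnames(res)))

    # identical constant groups: t = 0, p = 1
    dcq0 <- data.frame(sample = sprintf("s%d", 1:8),
                       group = rep(c("a", "b"), each = 4),
                       gene = "g1", dcq = rep(2, 8))
    res0 <- expressionTests(dcq0, comparisons = list(c("b", "a")))
    expect_equal(res0$t, 0)
    expect_equal(res0$p, 1)
})

test_that("q-values reduce to BH at pi0 = 1 and match the oracle", {
    set.seed(6)
    p <- runif(40)
    expect_equal(as.numeric(storeyQvalues(p, pi0 = 1)), adjustBH(p))
    expect_equal(as.numeric(storeyQvalues(rep(1, 5), pi0 = 1)), rep(1, 5))

    p2 <- c(runif(80), runif(20, 0, 1e-4))
    q <- storeyQvalues(p2)
    expect_equal(as.numeric(q), oracleStorey(p2), tolerance = 1e-10)
    expect_equal(attr(q, "pi0"), attr(q, "pi0"))
    # monotone in p and bounded below by pi0-scaled BH
    o <- order(p2)
    expect_true(all(diff(as.numeric(q)[o]) >= -1e-12))
    expect_true(all(q >= attr(q, "pi0") * adjustBH(p2) - 1e-12))
    expect_message(storeyQvalues(0.5), "pi0 fixed at 1")
    expect_error(storeyQvalues(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("morphometric tests dispatch to the right rank test", {
    same <- list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2))
    kw <- morphometricTests(same, "multi_group")
    expect_equal(kw$statistic, 0)

    sep <- morphometricTests(list(hi = c(4, 5, 6), lo = c(1, 2, 3)),
                             "two_group")
    expect_equal(sep$statistic, 9)   # fully separated: W = n1 * n2

    vals <- list(g1 = c(1, 3, 5), g2 = c(2, 4, 8), g3 = c(6, 7, 9))
    kw2 <- morphometricTests(vals, "multi_group")
    r <- rank(unlist(vals))
    n <- 9
    hand <- 12 / (n * (n + 1)) *
        sum(tapply(r, rep(names(vals), each = 3), function(x)
            length(x) * (mean(x) - (n + 1) / 2)^2))
    expect_equal(kw2$statistic, hand)
    expect_error(morphometricTests(list(a = 1:3), "two_group"), "2 groups")
    expect_error(morphometricTests(list(a = 1:3, b = numeric(0)),
                                   "two_group"), "at least one value")
})

test_that("noiseless recovery holds at every amplification efficiency", {
    for (E in c(1, 0.85)) {
        sim <- simulateQpcr(qpcrSimConfig(
            genes = "tgt", trueLog2fc = c(tgt = 1.5), efficiencies = E,
            noiseSd = 0, seed = 4))
        res <- expressionTests(deltaCq(sim$experiment),
                               comparisons = list(c("treatment", "control")))
        expect_equal(res$log2fc, 1.5, tolerance = 1e-12)
    }
})
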