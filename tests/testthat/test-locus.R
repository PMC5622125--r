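mslFromCounts <- function(counts) {
    # counts: 2 x G matrix (methylated / unmethylated per group)
    G <- ncol(counts)
    states <- integer(0)
    group <- character(0)
    for (g in seq_len(G)) {
        states <- c(states, rep(1L, counts[1, g]), rep(0L, counts[2, g]))
        group <- c(group, rep(sprintf("g%d", g), sum(counts[, g])))
    }
    makeMsl(matrix(states, 1, length(states)), group)
}

test_that("two-group Fisher p-values match hypergeometric enumeration", {
    expect_equal(locusFisherTests(
        mslFromCounts(rbind(c(5, 5), c(5, 5))))$p_raw, 1)
    expect_equal(locusFisherTests(
        mslFromCounts(rbind(c(3, 0), c(0, 3))))$p_raw, 0.1)
    set.seed(8)
    for (i in 1:20) {
        tab <- matrix(rpois(4, 5) + 1L, 2)
        if (sum(tab) > 30) next
        got <- locusFisherTests(mslFromCounts(tab))$p_raw
        expect_equal(got, oracleFisher22(tab), tolerance = 1e-12,
                     info = paste(tab, collapse = ","))
    }
})

test_that("three-group exact p-values match full-margin enumeration", {
    set.seed(9)
    for (i in 1:10) {
        tab <- matrix(rpois(6, 4) + 1L, 2)
        got <- locusFisherTests(mslFromCounts(tab))$p_raw
        expect_equal(got, oracleFisher23(tab), tolerance = 1e-7,
                     info = paste(tab, collapse = ","))
    }
})

test_that("per-locus tests apply BH jointly and flag at the threshold", {
    sim <- simulateMsap(msapSimConfig(groupSizes = c(12, 12), nLoci = 150,
                                      diffFraction = 0.3, effectSize = 0.6,
                                      seed = 51))
    cls <- classifyLoci(callMethylationTypes(sim$experiment))
    lt <- locusFisherTests(cls$msl, alpha = 0.05)
    expect_identical(nrow(lt), nrow(cls$msl))
    expect_equal(lt$p_adj, p.adjust(lt$p_raw, "BH"))
    expect_true(all(lt$p_adj >= lt$p_raw))
    expect_identical(lt$significant, lt$p_adj < 0.05)
    # significance count is non-increasing as alpha decreases
    n05 <- sum(locusFisherTests(cls$msl, alpha = 0.05)$significant)
    n01 <- sum(locusFisherTests(cls$msl, alpha = 0.01)$significant)
    n001 <- sum(locusFisherTests(cls$msl, alpha = 0.001)$significant)
    expect_true(n001 <= n01 && n01 <= n05)
    expect_gt(n05, 0)
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(0.37), 0.37)
    expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significant-locus intersection behaves as a set operation", {
    mk <- function(loci, sig) data.frame(locus = loci,
                                         significant = loci %in% sig)
    a <- mk(sprintf("L%d", 1:10), sprintf("L%d", 1:4))
    b <- mk(sprintf("L%d", 1:10), sprintf("L%d", 3:6))
    expect_identical(intersectSignificant(a, b), c("L3", "L4"))
    # A subset of B -> A
    b2 <- mk(sprintf("L%d", 1:10), sprintf("L%d", 1:8))
    expect_identical(intersectSignificant(a, b2), sprintf("L%d", 1:4))
    # disjoint significant sets -> empty
    b3 <- mk(sprintf("L%d", 1:10), sprintf("L%d", 7:8))
    expect_identical(intersectSignificant(a, b3), character(0))
    # disjoint namespaces -> warning and empty set
    c1 <- mk(sprintf("M%d", 1:5), "M1")
    expect_warning(out <- intersectSignificant(a, c1), "no loci")
    expect_identical(out, character(0))
})

test_that("Gower distance is the categorical mismatch fraction", {
    types <- rbind(c(1L, 2L, 3L, 4L),
                   c(1L, 2L, 3L, 4L),
                   c(2L, 3L, 4L, 1L),
                   c(1L, 2L, 4L, 1L))
    x <- makeCalls(types, group = rep("A", 4))
    d <- gowerDistance(x)
    expect_equal(d["L01", "L02"], 0)
    expect_equal(d["L01", "L03"], 1)
    expect_equal(d["L01", "L04"], 0.5)
    # missing cells are excluded pairwise
    types2 <- rbind(c(1L, NA, 3L, 4L), c(1L, 2L, 4L, 4L))
    d2 <- gowerDistance(makeCalls(types2, group = rep("A", 4)))
    expect_equal(d2[1, 2], 1 / 3)
    # no jointly observed sample -> error naming the pair
    types3 <- rbind(c(1L, NA), c(NA, 2L))
    expect_error(gowerDistance(makeCalls(types3, group = c("A", "A"))),
                 "L01 and L02")
})

test_that("Gower distance satisfies the triangle inequality", {
    set.seed(14)
    types <- matrix(sample(1:4, 30 * 12, TRUE), 30, 12)
    d <- gowerDistance(makeCalls(types, group = rep("A", 12)))
    worst <- max(vapply(seq_len(nrow(d)), function(j)
        max(d - outer(d[, j], d[j, ], `+`)), 0))
    expect_lte(worst, 1e-12)
    expect_equal(d, t(d))
})

test_that("UPGMA merges by unweighted average with half-height nodes", {
    d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("x", "y"),
                                                  c("x", "y")))
    tr <- upgmaCluster(d)
    expect_equal(tr$height, 2)
    expect_equal(tr$nodeHeights, 1)

    d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C")))
    d3["A", "B"] <- d3["B", "A"] <- 2
    d3["A", "C"] <- d3["C", "A"] <- 4
    d3["B", "C"] <- d3["C", "B"] <- 6
    tr3 <- upgmaCluster(d3)
    expect_equal(tr3$height, c(2, 5))
    expect_equal(tr3$nodeHeights, c(1, 2.5))
    expect_identical(mergeSets(tr3), list(c("A", "B"), c("A", "B", "C")))
    expect_error(upgmaCluster(matrix(c(0, Inf, Inf, 0), 2)), "finite")
})

test_that("UPGMA matches the naive O(n^3) oracle on random matrices", {
    set.seed(33)
    for (rep in 1:6) {
        m <- matrix(runif(36), 6)
        d <- (m + t(m)) / 2
        diag(d) <- 0
        dimnames(d) <- list(letters[1:6], letters[1:6])
        tr <- upgmaCluster(d)
        ora <- oracleUpgma(d)
        expect_identical(mergeSets(tr), ora$merges)
        expect_equal(tr$height, ora$heights)
    }
})

test_that("UPGMA agrees with hclust average linkage when ties are absent", {
    set.seed(2)
    m <- matrix(runif(64), 8)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(LETTERS[1:8], LETTERS[1:8])
    tr <- upgmaCluster(d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(tr$height), sort(hc$height))
    expect_equal(cophenetic(structure(unclass(tr), class = "hclust")),
                 cophenetic(hc))
})

test_that("Newick serialization preserves the ultrametric tree", {
    d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C")))
    d3["A", "B"] <- d3["B", "A"] <- 2
    d3["A", "C"] <- d3["C", "A"] <- 4
    d3["B", "C"] <- d3["C", "B"] <- 6
    txt <- writeNewick(upgmaCluster(d3))
    phy <- ape::read.tree(text = txt)
    expect_setequal(phy$tip.label, c("A", "B", "C"))
    # cophenetic distances on the tree equal the UPGMA merge distances
    cd <- ape::cophenetic.phylo(phy)
    expect_equal(cd["A", "B"], 2)
    expect_equal(cd["A", "C"], 5)

    path <- withr::local_tempfile(fileext = ".nwk")
    writeNewick(upgmaCluster(d3), path)
    expect_identical(readLines(path), txt)
})
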