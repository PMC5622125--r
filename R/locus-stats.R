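#' Per-locus Fisher exact tests with Benjamini-Hochberg FDR control
#'
#' For each polymorphic MSL, a two-sided exact test on the 2 x G contingency
#' table of methylated vs unmethylated counts per group (missing cells
#' excluded).  For G > 2 the exact test sums the probabilities, under fixed
#' margins, of all tables at most as probable as the observed one.  Above the
#' enumeration budget a seeded Monte-Carlo p-value is used instead (and
#' noted).  P-values are adjusted jointly across all loci by the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param x a [MslBinaryMatrix-class] object (>= 2 groups).
#' @param alpha FDR threshold in (0, 1) for the significance flag.
#' @param workspace enumeration budget handed to the exact-test network
#'   algorithm.
#' @param simulateB Monte-Carlo draw count for the fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A data.frame with one row per locus: locus, per-group methylated /
#'   unmethylated counts, p_raw, p_adj, significant, monte_carlo flag; the
#'   threshold is stored as attribute \code{"alpha"}.
#' @export
locusFisherTests <- function(x, alpha = 0.05, workspace = 2e5,
                             simulateB = 1e5, seed = 1L) {
    stopifnot(is(x, "MslBinaryMatrix"))
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
    grp <- sampleGroups(x)
    lv <- sort(unique(grp))
    if (length(lv) < 2L)
        stop("need >= 2 groups")
    states <- mslStates(x)
    nLoci <- nrow(states)
    p <- numeric(nLoci)
    mc <- logical(nLoci)
    counts <- matrix(0L, nLoci, 2L * length(lv),
                     dimnames = list(NULL, c(paste0("meth_", lv),
                                             paste0("unmeth_", lv))))
    for (i in seq_len(nLoci)) {
        tab <- matrix(0L, 2L, length(lv))
        for (j in seq_along(lv)) {
            s <- states[i, grp == lv[j]]
            tab[1L, j] <- sum(s == 1L, na.rm = TRUE)
            tab[2L, j] <- sum(s == 0L, na.rm = TRUE)
        }
        counts[i, ] <- c(tab[1L, ], tab[2L, ])
        if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
            # degenerate margin: no information against homogeneity
            message("locus ", rownames(states)[i],
                    ": zero margin, p set to 1")
            p[i] <- 1
            next
        }
        ft <- tryCatch(
            stats::fisher.test(tab, workspace = workspace),
            error = function(e) NULL)
        if (is.null(ft)) {
            mc[i] <- TRUE
            ft <- withSeed(deriveSeed(seed, rownames(states)[i]),
                stats::fisher.test(tab, simulate.p.value = TRUE,
                                   B = simulateB))
        }
        # the network algorithm can return 1 + eps; clamp to [0, 1]
        p[i] <- min(max(ft$p.value, 0), 1)
    }
    if (any(mc))
        message(sum(mc), " locus/loci used a Monte-Carlo p-value ",
                "(enumeration budget exceeded)")
    padj <- adjustBH(p)
    out <- data.frame(locus = rownames(states), counts,
                      p_raw = p, p_adj = padj,
                      significant = padj < alpha, monte_carlo = mc,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "alpha") <- alpha
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input validation plus the standard step-up rule: sort p ascending, take
#' p * m / rank, enforce monotonicity from the largest down, cap at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
adjustBH <- function(p) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
        stop("'p' must be p-values in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Loci significant in both of two comparisons
#'
#' @param tableA,tableB results of [locusFisherTests()] over a shared locus
#'   namespace.
#' @return Character vector of loci flagged significant in both tables.
#' @export
intersectSignificant <- function(tableA, tableB) {
    sigA <- tableA$locus[tableA$significant]
    sigB <- tableB$locus[tableB$significant]
    if (!length(intersect(tableA$locus, tableB$locus)))
        warning("tables share no loci; returning an empty set")
    intersect(sigA, sigB)
}

#' Gower distance between loci over categorical methylation types
#'
#' For purely categorical variables Gower's coefficient reduces to the
#' fraction of mismatching features: the distance between two loci is the
#' proportion of samples (with both cells non-missing) whose types I--IV
#' differ.
#'
#' @param x a [MethylationCalls-class] object.
#' @param loci optional character vector restricting to chosen loci (e.g.
#'   significant ones); default all.
#' @return Loci x loci symmetric matrix of distances in [0, 1].
#' @export
gowerDistance <- function(x, loci = NULL) {
    stopifnot(is(x, "MethylationCalls"))
    tp <- assay(x, "type")
    if (!is.null(loci)) {
        missing <- setdiff(loci, rownames(tp))
        if (length(missing))
            stop("unknown loci: ", paste(missing, collapse = ", "))
        tp <- tp[loci, , drop = FALSE]
    }
    n <- nrow(tp)
    if (n < 2L)
        stop("at least 2 loci are required")
    d <- matrix(0, n, n, dimnames = list(rownames(tp), rownames(tp)))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            ok <- !is.na(tp[i, ]) & !is.na(tp[j, ])
            if (!any(ok))
                stop(sprintf("loci %s and %s share no non-missing sample",
                             rownames(tp)[i], rownames(tp)[j]))
            d[i, j] <- d[j, i] <- mean(tp[i, ok] != tp[j, ok])
        }
    }
    d
}

#' UPGMA hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative average-linkage clustering, unweighted on leaves: the
#' distance between clusters is the arithmetic mean of all cross-pair leaf
#' distances.  At each step the closest pair is merged; exact ties are broken
#' lexicographically by the smallest leaf label in each cluster, making the
#' merge sequence fully deterministic.  Merge heights are cophenetic
#' distances (hclust convention); the corresponding ultrametric node heights
#' are half the merge distance, which is the branch-length convention used
#' when the tree is serialized.
#'
#' @param d loci x loci symmetric matrix of finite distances (e.g. from
#'   [gowerDistance()]).
#' @return An object of class \code{c("upgmaTree", "hclust")} with the usual
#'   \code{merge}, \code{height}, \code{labels}, \code{order} components plus
#'   \code{nodeHeights} (= height / 2).
#' @seealso [writeNewick()]
#' @export
upgmaCluster <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2L)
        stop("at least 2 leaves are required")
    if (any(!is.finite(d)))
        stop("distances must be finite")
    labels <- rownames(d)
    if (is.null(labels))
        labels <- sprintf("t%d", seq_len(n))
    # active cluster bookkeeping: member leaves, representative (min) label,
    # merge-matrix id (negative = singleton leaf)
    members <- as.list(seq_len(n))
    repLabel <- labels
    id <- -seq_len(n)
    active <- rep(TRUE, n)
    cd <- d
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    nodeOf <- vector("list", n - 1L)
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        best <- NULL
        bestD <- Inf
        for (ii in seq_along(idx)[-length(idx)]) {
            for (jj in (ii + 1L):length(idx)) {
                a <- idx[ii]; b <- idx[jj]
                dd <- cd[a, b]
                pick <- FALSE
                if (dd < bestD - 1e-12) {
                    pick <- TRUE
                } else if (abs(dd - bestD) <= 1e-12) {
                    # tie: prefer lexicographically smaller (repA, repB) pair
                    cur <- sort(c(repLabel[a], repLabel[b]))
                    old <- sort(c(repLabel[best[1L]], repLabel[best[2L]]))
                    if (cur[1L] < old[1L] ||
                        (cur[1L] == old[1L] && cur[2L] < old[2L]))
                        pick <- TRUE
                }
                if (pick) {
                    best <- c(a, b)
                    bestD <- dd
                }
            }
        }
        a <- best[1L]; b <- best[2L]
        # put lexicographically smaller representative first
        if (repLabel[b] < repLabel[a]) { tmp <- a; a <- b; b <- tmp }
        merge[step, ] <- c(id[a], id[b])
        height[step] <- bestD
        nodeOf[[step]] <- c(members[[a]], members[[b]])
        na <- length(members[[a]]); nb <- length(members[[b]])
        for (k in idx) {
            if (k == a || k == b) next
            cd[a, k] <- cd[k, a] <- (na * cd[a, k] + nb * cd[b, k]) /
                (na + nb)
        }
        members[[a]] <- c(members[[a]], members[[b]])
        id[a] <- step
        active[b] <- FALSE
    }
    ord <- .leafOrder(merge, n)
    structure(list(merge = merge, height = height, order = ord,
                   labels = labels, nodeHeights = height / 2,
                   method = "upgma", call = match.call(),
                   dist.method = "user-supplied"),
              class = c("upgmaTree", "hclust"))
}

# Leaf ordering by left-to-right traversal of the merge matrix.
.leafOrder <- function(merge, n) {
    rec <- function(node) {
        if (node < 0L)
            return(-node)
        c(rec(merge[node, 1L]), rec(merge[node, 2L]))
    }
    rec(nrow(merge))
}

#' Serialize an UPGMA tree as Newick
#'
#' Branch lengths follow the ultrametric convention: node heights are half
#' the merge distance, so the leaf-to-leaf path length through their common
#' ancestor equals the cophenetic (merge) distance.
#'
#' @param tree an object from [upgmaCluster()] (or any \code{hclust}).
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
    phy <- ape::as.phylo(stats::as.hclust(
        structure(unclass(tree), class = "hclust")))
    txt <- ape::write.tree(phy)
    if (is.null(path))
        return(txt)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "\n")
    invisible(txt)
}
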