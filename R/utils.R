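## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded APIs do not perturb user sessions.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has)
            old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (has)
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# Deterministic per-stage seed derivation from a single run seed: keeps all
# stages reproducible from one integer while decorrelating their streams.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.checkFraction <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a single value in [0, 1]", what))
    x
}

# Fixed-format table writer used by the pipeline: identical input always
# yields byte-identical files (LF endings, 15 significant digits).
writeTsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    fmt <- vapply(df, function(col) {
        if (is.numeric(col) && !is.integer(col))
            sprintf("%.15g", col)
        else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L)
        fmt <- matrix(fmt, nrow = 1L)
    fmt[is.na(df)] <- "NA"
    lines <- c(paste(colnames(df), collapse = "\t"),
               apply(fmt, 1L, paste, collapse = "\t"))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}
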