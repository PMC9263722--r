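`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so simulators are seeded without
# clobbering the caller's stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Derive a reproducible per-stage seed from a root seed
#'
#' Each pipeline stage draws its randomness from a seed deterministically
#' derived from the run's root seed and the stage name, so any stage can be
#' re-run in isolation.
#'
#' @param seed root integer seed.
#' @param stage stage name (character scalar).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
    as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483646)
}

#' Read / write gene-by-sample expression TSV
#'
#' Plain TSV with gene ids in the first column and a header row of sample
#' ids, the interchange format used by all command-line entry points.
#'
#' @param path file path.
#' @param x numeric matrix with dimnames (for writing).
#' @return `readExpressionTSV` returns a numeric matrix.
#' @export
readExpressionTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    as.matrix(df)
}

#' @rdname readExpressionTSV
#' @export
writeExpressionTSV <- function(x, path) {
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

writeTableTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# Renumber integer cluster labels by decreasing cluster size; ties broken by
# the smallest member index so the naming is deterministic.
renumberBySize <- function(labels) {
    sizes <- table(labels)
    firstMember <- vapply(names(sizes), function(l) min(which(labels == l)), 0L)
    ord <- order(-as.integer(sizes), firstMember)
    map <- stats::setNames(seq_along(ord), names(sizes)[ord])
    out <- map[as.character(labels)]
    names(out) <- names(labels)
    out
}
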