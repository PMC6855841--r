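# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Children adjacency list of a phylo tree, indexed by node number.
childrenList <- function(phy) {
    n <- ape::Ntip(phy) + phy$Nnode
    out <- vector("list", n)
    for (i in seq_len(nrow(phy$edge)))
        out[[phy$edge[i, 1L]]] <- c(out[[phy$edge[i, 1L]]], phy$edge[i, 2L])
    out
}

# Tip labels descending from (or equal to) `node`.
descendantTips <- function(phy, node) {
    ntip <- ape::Ntip(phy)
    if (node <= ntip)
        return(phy$tip.label[node])
    kids <- childrenList(phy)
    acc <- integer()
    stack <- node
    while (length(stack)) {
        v <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        if (v <= ntip) acc <- c(acc, v) else stack <- c(stack, kids[[v]])
    }
    phy$tip.label[sort(acc)]
}

# Write a data.frame as the canonical TSV dialect (tab-separated, header,
# UTF-8, "." decimal, no quoting). Numerics keep full precision.
writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    for (j in which(num))
        df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.delim(path, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
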