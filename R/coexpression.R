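# k-means++ seeding: spread initial centers by squared-distance sampling.
kmeansPPCenters <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    i <- sample.int(n, 1L)
    centers[1L, ] <- X[i, ]
    d2 <- rowSums((X - rep(centers[1L, ], each = n))^2)
    for (j in seq_len(k - 1L) + 1L) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        i <- sample.int(n, 1L, prob = p)
        centers[j, ] <- X[i, ]
        d2 <- pmin(d2, rowSums((X - rep(centers[j, ], each = n))^2))
    }
    centers
}

# One k-means partition; returns integer labels. Duplicate seeded centers
# (possible when distinct points are fewer than k) are collapsed.
baseKmeans <- function(X, k) {
    centers <- unique(kmeansPPCenters(X, k))
    km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 50L))
    km$cluster
}

#' Consensus co-expression clustering with an unassigned remainder
#'
#' Runs k-means base learners across a grid of k values and random seeds
#' on the normalized profiles (replicates concatenated as additional
#' dimensions), accumulates a gene-by-gene co-assignment frequency matrix,
#' and greedily extracts tight clusters: each cluster is seeded at the
#' remaining pair with the highest co-assignment frequency and grown by
#' repeatedly admitting the gene with the highest mean frequency to the
#' current members, for as long as that mean stays at or above `tau`.
#' Extracted groups smaller than `minSize` are discarded, so genes that do
#' not conform to any tight temporal program are left unassigned rather
#' than forced into a cluster. Deterministic given `seed`.
#'
#' @param norm a [TimecourseExperiment-class] carrying a `normalized`
#'   assay (see [normalizeExpression()]).
#' @param kGrid integer vector of k values for the base learners.
#' @param nBaseRuns random restarts per k.
#' @param tau consensus threshold in (0, 1]: minimum co-assignment
#'   frequency for a pair to be linked. Raising it can only shrink
#'   clusters, never grow the assigned set.
#' @param minSize minimum cluster size (default 10).
#' @param seed RNG seed.
#' @return list with `assignment` (data.frame `gene_id`, `cluster`; NA =
#'   unassigned, clusters numbered by decreasing size), `nClusters`,
#'   `sizes`, and `coassignment` (the frequency matrix).
#' @export
consensusCluster <- function(norm, kGrid = 5:15, nBaseRuns = 20,
                             tau = 0.7, minSize = 10, seed = 1L) {
    X <- assay(norm, "normalized")
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 genes")
    if (ncol(X) < 3L) stop("need at least 3 timepoints")
    if (any(kGrid >= n))
        stop("kGrid contains k >= number of genes (", n, ")")
    if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
    C <- matrix(0, n, n)
    withSeed(seed, {
        for (k in kGrid) {
            for (run in seq_len(nBaseRuns)) {
                cl <- baseKmeans(X, k)
                Z <- outer(cl, seq_len(max(cl)), "==")
                C <- C + tcrossprod(Z * 1)
            }
        }
    })
    C <- C / (length(kGrid) * nBaseRuns)
    diag(C) <- 0
    cluster <- rep(NA_integer_, n)
    groups <- list()
    active <- rep(TRUE, n)
    W <- C
    repeat {
        if (!any(active)) break
        top <- which.max(W)             # first maximum: deterministic
        if (W[top] < tau) break
        i <- ((top - 1L) %% n) + 1L
        j <- ((top - 1L) %/% n) + 1L
        members <- c(min(i, j), max(i, j))
        inMem <- rep(FALSE, n)
        inMem[members] <- TRUE
        sums <- C[, members[1L]] + C[, members[2L]]
        repeat {
            cand <- which(active & !inMem)
            if (!length(cand)) break
            best <- cand[which.max(sums[cand])]
            if (sums[best] / length(members) < tau) break
            members <- c(members, best)
            inMem[best] <- TRUE
            sums <- sums + C[, best]
        }
        groups[[length(groups) + 1L]] <- sort(members)
        active[members] <- FALSE
        W[members, ] <- 0
        W[, members] <- 0
    }
    groups <- groups[lengths(groups) >= minSize]
    # label clusters by decreasing size; ties broken by first member index
    ord <- order(-lengths(groups), vapply(groups, min, 0L))
    for (i in seq_along(ord))
        cluster[groups[[ord[i]]]] <- i
    diag(C) <- 1
    dimnames(C) <- list(rownames(X), rownames(X))
    list(assignment = data.frame(gene_id = rownames(X),
                                 cluster = cluster,
                                 stringsAsFactors = FALSE),
         nClusters = length(ord),
         sizes = lengths(groups)[ord],
         coassignment = C)
}

#' Robustness of cluster membership across replicates
#'
#' Re-runs the consensus clustering on replicate 1 alone, replicate 2
#' alone, and the per-timepoint average of the replicates, and reports the
#' pairwise adjusted Rand index over genes assigned in both runs of a
#' pair.
#'
#' @param x a filtered [TimecourseExperiment-class] (tpm assay) with >= 2
#'   replicates.
#' @param ... arguments passed on to [consensusCluster()].
#' @param seed RNG seed.
#' @return data.frame with columns `run1`, `run2`, `ari`, `nShared`.
#' @export
replicateRobustness <- function(x, ..., seed = 1L) {
    cd <- colData(x)
    reps <- sort(unique(cd$replicate))
    if (length(reps) < 2L) stop("need at least 2 replicates")
    sub1 <- x[, cd$replicate == reps[1L]]
    sub2 <- x[, cd$replicate == reps[2L]]
    common <- intersect(sampleTimepoints(sub1), sampleTimepoints(sub2))
    s1 <- sub1[, match(common, sampleTimepoints(sub1))]
    s2 <- sub2[, match(common, sampleTimepoints(sub2))]
    mAvg <- (tpm(s1) + tpm(s2)) / 2
    colnames(mAvg) <- paste0("t", common, "_avg")
    avg <- timecourseExperiment(mAvg, timepoint = common,
                                replicate = rep(1L, length(common)))
    runs <- list(replicate1 = s1, replicate2 = s2, average = avg)
    asg <- lapply(seq_along(runs), function(i) {
        consensusCluster(normalizeExpression(runs[[i]]), ...,
                         seed = seed + i)$assignment
    })
    names(asg) <- names(runs)
    pairs <- utils::combn(names(runs), 2L)
    out <- data.frame(run1 = pairs[1L, ], run2 = pairs[2L, ],
                      ari = NA_real_, nShared = NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(ncol(pairs))) {
        a <- asg[[pairs[1L, i]]]
        b <- asg[[pairs[2L, i]]]
        b <- b[match(a$gene_id, b$gene_id), ]
        shared <- !is.na(a$cluster) & !is.na(b$cluster)
        out$nShared[i] <- sum(shared)
        out$ari[i] <- mclust::adjustedRandIndex(a$cluster[shared],
                                                b$cluster[shared])
    }
    out
}

#' Mean and dispersion profile of each co-expression cluster
#'
#' @param norm the [TimecourseExperiment-class] the assignment was
#'   computed on (uses the `normalized` assay).
#' @param assignment data.frame `gene_id`, `cluster` from
#'   [consensusCluster()].
#' @return data.frame with one row per (cluster, replicate, timepoint):
#'   `mean` and `sd` of member profiles. Empty clusters are dropped with a
#'   warning.
#' @export
meanClusterProfiles <- function(norm, assignment) {
    z <- assay(norm, "normalized")
    assignment <- assignment[match(rownames(z), assignment$gene_id), ]
    ids <- sort(unique(stats::na.omit(assignment$cluster)))
    empty <- setdiff(ids, assignment$cluster)
    if (length(empty))
        warning("dropping empty cluster(s): ", paste(empty, collapse = ", "))
    cd <- colData(norm)
    out <- do.call(rbind, lapply(ids, function(cc) {
        mem <- z[which(assignment$cluster == cc), , drop = FALSE]
        data.frame(cluster = cc,
                   replicate = cd$replicate,
                   timepoint = cd$timepoint,
                   mean = colMeans(mem),
                   sd = apply(mem, 2L, stats::sd),
                   row.names = NULL)
    }))
    out
}
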