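#' Remove genes transcribed at very low levels
#'
#' Drops genes whose arithmetic mean tpm across all samples of both
#' replicates is strictly below `threshold`; genes at exactly the
#' threshold are retained. Retained values are untouched and gene order is
#' preserved.
#'
#' @param x a [TimecourseExperiment-class].
#' @param threshold tpm threshold (default 0.5).
#' @return the filtered [TimecourseExperiment-class].
#' @export
filterLowExpression <- function(x, threshold = 0.5) {
    if (threshold < 0) stop("threshold must be >= 0")
    keep <- rowMeans(tpm(x)) >= threshold
    if (!any(keep))
        warning("no gene passes the expression filter")
    x[keep, ]
}

#' Shift replicate-2 timepoint labels to align developmental programs
#'
#' Adds `shiftHours` to the timepoint labels of the second replicate (as in
#' re-dating a lagging replicate after inspecting the sample dendrogram)
#' and drops samples whose shifted time is not observed in replicate 1.
#'
#' @param x a [TimecourseExperiment-class] with >= 2 replicates.
#' @param shiftHours signed shift; must be an integer multiple of the
#'   sampling interval. 0 returns the input unchanged.
#' @return the realigned [TimecourseExperiment-class].
#' @export
alignReplicates <- function(x, shiftHours) {
    if (shiftHours == 0) return(x)
    cd <- colData(x)
    reps <- sort(unique(cd$replicate))
    if (length(reps) < 2L)
        stop("alignReplicates needs at least 2 replicates")
    t1 <- sort(cd$timepoint[cd$replicate == reps[1L]])
    interval <- unique(diff(t1))
    if (length(interval) != 1L || abs(shiftHours / interval -
                                      round(shiftHours / interval)) > 1e-9)
        stop("shiftHours must be an integer multiple of the sampling ",
             "interval (", paste(interval, collapse = ", "), " hr)")
    isR2 <- cd$replicate == reps[2L]
    newT <- cd$timepoint
    newT[isR2] <- newT[isR2] + shiftHours
    drop <- isR2 & !(newT %in% t1)
    if (any(drop))
        message("alignReplicates: dropping ", sum(drop),
                " replicate-2 sample(s) outside the common time window: ",
                paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop]
    cd2 <- colData(x)
    cd2$timepoint <- newT[!drop]
    colData(x) <- cd2
    x[, order(cd2$replicate, cd2$timepoint)]
}

#' Cluster samples by Euclidean distance of Spearman correlations
#'
#' Computes the Spearman correlation between every pair of samples over
#' genes, takes as the distance between two samples the Euclidean distance
#' between their rows of the correlation matrix, and clusters samples
#' agglomeratively (average linkage).
#'
#' @param x a [TimecourseExperiment-class] with >= 2 samples.
#' @param useAssay assay to correlate (default `"tpm"`).
#' @return an [stats::hclust] dendrogram with sample ids as labels.
#' @export
sampleCorrelationClustering <- function(x, useAssay = "tpm") {
    if (ncol(x) < 2L) stop("need at least 2 samples")
    m <- assay(x, useAssay)
    sdv <- apply(m, 2L, stats::sd)
    rho <- suppressWarnings(stats::cor(m, method = "spearman"))
    if (any(sdv == 0)) {
        warning("constant sample(s), correlations set to 0: ",
                paste(colnames(m)[sdv == 0], collapse = ", "))
        rho[sdv == 0, ] <- 0
        rho[, sdv == 0] <- 0
        diag(rho) <- 1
    }
    stats::hclust(stats::dist(rho), method = "average")
}

#' Write a sample dendrogram as newick plus a merge table
#'
#' @param hc an [stats::hclust] object.
#' @param newickPath,mergePath output paths (either may be NULL to skip).
#' @export
writeDendrogram <- function(hc, newickPath = NULL, mergePath = NULL) {
    if (!is.null(newickPath))
        ape::write.tree(ape::as.phylo(hc), newickPath)
    if (!is.null(mergePath))
        writeTsv(data.frame(step = seq_along(hc$height),
                            left = hc$merge[, 1L], right = hc$merge[, 2L],
                            height = hc$height), mergePath)
    invisible(hc)
}

#' Normalize expression profiles for co-expression clustering
#'
#' Per gene: `log2(tpm + 1)`, then centring and scaling to mean 0 and
#' standard deviation 1 across samples. Genes with zero variance after the
#' log transform cannot be standardized; they are excluded and recorded in
#' `metadata(x)$excludedGenes`.
#'
#' @param x a filtered [TimecourseExperiment-class].
#' @return a [TimecourseExperiment-class] restricted to the normalizable
#'   genes, carrying assays `tpm` and `normalized`.
#' @export
normalizeExpression <- function(x) {
    lg <- log2(tpm(x) + 1)
    sdv <- apply(lg, 1L, stats::sd)
    excluded <- rownames(x)[sdv == 0]
    if (length(excluded))
        message("normalizeExpression: excluding ", length(excluded),
                " zero-variance gene(s)")
    keep <- sdv > 0
    z <- (lg[keep, , drop = FALSE] -
          rowMeans(lg[keep, , drop = FALSE])) / sdv[keep]
    out <- x[keep, ]
    assays(out) <- c(assays(out), list(normalized = z))
    metadata(out)$excludedGenes <- excluded
    out
}
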