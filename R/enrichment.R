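#' Fisher's exact test on a 2x2 contingency table
#'
#' Cells follow the (set, cluster) layout: `a` = in-set and in-cluster,
#' `b` = in-set only, `c` = in-cluster only, `d` = neither. P-values are
#' the exact hypergeometric ones (one-sided = P(X >= a) given the margins,
#' the enrichment direction; two-sided = sum of table probabilities no
#' larger than the observed one). The odds ratio is the sample odds ratio
#' `ad/bc`, infinite when `bc = 0` with `a, d > 0`.
#'
#' @param a,b,c,d non-negative integer cell counts; alternatively pass a
#'   2x2 matrix as `a`.
#' @return data.frame (one row): `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_one`, `p_two`.
#' @examples
#' fisher2x2(10, 0, 0, 10)$p_two  # 2 / choose(20, 10)
#' @export
fisher2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == 2L))
        d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
    }
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) ||
        any(cells != round(cells)))
        stop("cells must be non-negative integers")
    tab <- matrix(as.integer(cells), 2L, 2L, byrow = TRUE)
    pOne <- stats::fisher.test(tab, alternative = "greater")$p.value
    pTwo <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    or <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c)
    data.frame(a = a, b = b, c = c, d = d, odds_ratio = or,
               p_one = pOne, p_two = pTwo)
}

#' Enrichment of phylostrata within co-expression clusters
#'
#' For every (cluster, stratum) pair, builds the 2x2 table of stratum
#' membership against cluster membership over the full gene universe (all
#' genes of the assignment, assigned or not) and applies [fisher2x2()].
#' One-sided p-values (enrichment direction) are Benjamini-Hochberg
#' adjusted across the whole cluster-by-stratum family.
#'
#' @param ages gene-age table with `gene_id` and `stratum`.
#' @param assignment data.frame `gene_id`, `cluster` (NA = unassigned)
#'   from [consensusCluster()].
#' @param adjust apply BH adjustment (default TRUE; raw p's are always
#'   reported).
#' @return data.frame with one row per (cluster, stratum): cell counts,
#'   `odds_ratio`, `p_one`, `p_two`, `p_adj`.
#' @export
stratumClusterEnrichment <- function(ages, assignment, adjust = TRUE) {
    ps <- ages$stratum[match(assignment$gene_id, ages$gene_id)]
    if (anyNA(ps))
        stop("gene(s) in the assignment without an age")
    clusters <- sort(unique(stats::na.omit(assignment$cluster)))
    strata <- sort(unique(ps))
    rows <- list()
    for (cc in clusters) {
        inClust <- !is.na(assignment$cluster) & assignment$cluster == cc
        for (s in strata) {
            inStr <- ps == s
            r <- fisher2x2(sum(inStr & inClust), sum(inStr & !inClust),
                           sum(!inStr & inClust), sum(!inStr & !inClust))
            rows[[length(rows) + 1L]] <-
                cbind(data.frame(cluster = cc, stratum = s), r)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adj <- if (adjust) stats::p.adjust(out$p_one, "BH") else out$p_one
    out
}

#' Fisher enrichment of the overlap of two gene sets
#'
#' Builds the 2x2 table of membership in `setA` against membership in
#' `setB` over `universe` and applies [fisher2x2()]. Used e.g. to ask
#' whether conserved lincRNAs fall into temporally co-expressed clusters
#' more often than expected by chance.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return one-row data.frame as from [fisher2x2()].
#' @export
setOverlapEnrichment <- function(setA, setB, universe) {
    if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
        stop("setA and setB must be subsets of the universe")
    inA <- universe %in% setA
    inB <- universe %in% setB
    fisher2x2(sum(inA & inB), sum(inA & !inB),
              sum(!inA & inB), sum(!inA & !inB))
}
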