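#' Build a SpeciesTree from a phylo object
#'
#' Walks the unique root-to-focal ancestor chain of a rooted tree and ranks
#' its nodes 1..S as phylostrata, with the root as stratum 1 (oldest) and
#' the focal leaf itself as stratum S (focal-species-specific).
#'
#' @param phy a rooted [ape::phylo] tree with unique leaf labels.
#' @param focal name of the focal leaf.
#' @param strataLabels optional character vector of stratum labels (root
#'   first); defaults to `PS1..PSS`, using node labels where present.
#' @return a [SpeciesTree-class] object.
#' @examples
#' phy <- ape::read.tree(text = "((((F,A),B),C),D);")
#' st <- speciesTree(phy, "F")
#' nStrata(st)   # 5
#' @export
speciesTree <- function(phy, focal, strataLabels = NULL) {
    if (!inherits(phy, "phylo"))
        stop("'phy' must be a phylo object")
    if (anyDuplicated(phy$tip.label))
        stop("tree leaf labels must be unique")
    if (!ape::is.rooted(phy))
        stop("tree must be rooted; midpoint or outgroup rooting is not guessed")
    if (!(focal %in% phy$tip.label))
        stop("focal leaf '", focal, "' not found; available leaves: ",
             paste(sort(phy$tip.label), collapse = ", "))
    ntip <- ape::Ntip(phy)
    focalTip <- match(focal, phy$tip.label)
    root <- ntip + 1L
    # ancestor chain focal -> root, then reversed
    parent <- integer(ntip + phy$Nnode)
    parent[phy$edge[, 2L]] <- phy$edge[, 1L]
    chain <- focalTip
    v <- focalTip
    while (v != root) {
        v <- parent[v]
        chain <- c(chain, v)
    }
    nodes <- rev(chain)
    if (is.null(strataLabels)) {
        strataLabels <- paste0("PS", seq_along(nodes))
        if (!is.null(phy$node.label)) {
            lab <- phy$node.label[nodes[nodes > ntip] - ntip]
            keep <- !is.na(lab) & nzchar(lab)
            strataLabels[which(nodes > ntip)][keep] <- lab[keep]
        }
    }
    if (length(strataLabels) != length(nodes))
        stop("strataLabels must have one label per stratum (",
             length(nodes), ")")
    new("SpeciesTree", tree = phy, focal = focal,
        strataNodes = as.integer(nodes),
        strataLabels = as.character(strataLabels))
}

#' Build a PhyleticMatrix
#'
#' @param presence matrix (orthogroups x species) of 0/1 values with
#'   dimnames set.
#' @param tree optional [SpeciesTree-class]; when given, species columns are
#'   validated against the tree leaves and presence in the focal species is
#'   enforced. Species in the tree but absent from the matrix are added as
#'   all-absent columns with a warning (robustness to partial proteomes).
#' @return a [PhyleticMatrix-class] object.
#' @export
phyleticMatrix <- function(presence, tree = NULL) {
    storage.mode(presence) <- "integer"
    if (!all(presence %in% c(0L, 1L)))
        stop("phyletic matrix cells must be 0 or 1")
    if (!is.null(tree)) {
        leaves <- tree@tree$tip.label
        unknown <- setdiff(colnames(presence), leaves)
        if (length(unknown))
            stop("species column(s) not in the tree: ",
                 paste(unknown, collapse = ", "))
        missing <- setdiff(leaves, colnames(presence))
        if (length(missing)) {
            warning("species in tree but absent from phyletic matrix, ",
                    "treated as all-absent: ",
                    paste(missing, collapse = ", "))
            add <- matrix(0L, nrow(presence), length(missing),
                          dimnames = list(rownames(presence), missing))
            presence <- cbind(presence, add)
        }
        presence <- presence[, leaves, drop = FALSE]
        absent <- presence[, focalSpecies(tree)] == 0L
        if (any(absent))
            stop("orthogroup(s) absent from the focal species: ",
                 paste(utils::head(rownames(presence)[absent], 5L),
                       collapse = ", "))
    }
    new("PhyleticMatrix", presence = presence)
}

#' Build a TimecourseExperiment
#'
#' @param tpm numeric genes-by-samples matrix of non-negative tpm values
#'   with gene rownames and sample colnames.
#' @param timepoint numeric vector of timepoints in hours, one per sample.
#' @param replicate vector of replicate ids, one per sample.
#' @return a [TimecourseExperiment-class] with samples ordered by
#'   (replicate, timepoint).
#' @export
timecourseExperiment <- function(tpm, timepoint, replicate) {
    if (any(tpm < 0))
        stop("negative tpm value(s) in gene(s): ",
             paste(utils::head(rownames(tpm)[rowSums(tpm < 0) > 0], 5L),
                   collapse = ", "))
    if (anyDuplicated(rownames(tpm)))
        stop("duplicate gene id(s): ",
             paste(unique(rownames(tpm)[duplicated(rownames(tpm))]),
                   collapse = ", "))
    ord <- order(replicate, timepoint)
    se <- SummarizedExperiment(
        assays = list(tpm = tpm[, ord, drop = FALSE]),
        colData = DataFrame(timepoint = as.numeric(timepoint)[ord],
                            replicate = replicate[ord],
                            row.names = colnames(tpm)[ord]))
    new("TimecourseExperiment", se)
}
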