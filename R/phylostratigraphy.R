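#' Dollo-parsimony gain node of a phyletic pattern
#'
#' Under Dollo parsimony a gene family is gained exactly once and may be
#' lost any number of times, so the unique most-parsimonious gain node is
#' the last common ancestor of all species carrying the gene. Because the
#' focal species is always among them, the gain node lies on the
#' root-to-focal chain and maps to a stratum rank.
#'
#' @param st a [SpeciesTree-class].
#' @param present character vector of species carrying the gene, or a named
#'   logical/0-1 vector over species.
#' @return list with `node` (ape node number), `stratum` (rank 1..S) and
#'   `label` (stratum label).
#' @examples
#' st <- speciesTree(ape::read.tree(text = "((((F,A),B),C),D);"), "F")
#' inferGainNode(st, c("F", "A", "B"))$stratum  # 3
#' @export
inferGainNode <- function(st, present) {
    if (is.logical(present) || is.numeric(present)) {
        if (is.null(names(present)))
            stop("a logical/0-1 presence vector must be named by species")
        present <- names(present)[as.logical(present)]
    }
    if (length(present) == 0L)
        stop("empty presence set: a gene must be present somewhere")
    phy <- st@tree
    unknown <- setdiff(present, phy$tip.label)
    if (length(unknown))
        stop("present species not in tree: ", paste(unknown, collapse = ", "))
    if (!(focalSpecies(st) %in% present))
        stop("focal species '", focalSpecies(st),
             "' absent from the presence pattern")
    node <- if (length(unique(present)) == 1L)
        match(present[1L], phy$tip.label)
    else
        ape::getMRCA(phy, unique(present))
    stratum <- match(node, st@strataNodes)
    # the MRCA of a focal-containing set is an ancestor-or-equal of the
    # focal leaf, hence always on the root-to-focal chain
    stopifnot(!is.na(stratum))
    list(node = node, stratum = stratum, label = st@strataLabels[stratum])
}

#' Assign phylostrata to focal-species genes
#'
#' Each gene inherits the stratum of its orthogroup's Dollo gain node
#' (the last common ancestor of the species carrying the orthogroup).
#' Genes with no orthogroup at all — no ortholog in any species — are
#' classified focal-species-specific (stratum S).
#'
#' @param pm a [PhyleticMatrix-class].
#' @param membership data.frame with columns `gene_id`, `orthogroup_id`
#'   (NA = no orthogroup).
#' @param st the [SpeciesTree-class] the matrix was validated against.
#' @return data.frame with one row per gene: `gene_id`, `orthogroup_id`,
#'   `stratum` (1 = oldest, S = focal-specific), `gain_node_label`.
#' @export
assignAges <- function(pm, membership, st) {
    if (anyDuplicated(membership$gene_id))
        stop("duplicate gene id(s) in membership table")
    known <- orthogroupIds(pm)
    bad <- setdiff(stats::na.omit(membership$orthogroup_id), known)
    if (length(bad))
        stop("gene(s) mapped to unknown orthogroup(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    m <- presence(pm)
    S <- nStrata(st)
    usedOg <- unique(stats::na.omit(membership$orthogroup_id))
    ogStratum <- vapply(usedOg, function(og) {
        inferGainNode(st, colnames(m)[m[og, ] == 1L])$stratum
    }, 0L)
    names(ogStratum) <- usedOg
    stratum <- ifelse(is.na(membership$orthogroup_id),
                      S, ogStratum[membership$orthogroup_id])
    data.frame(gene_id = membership$gene_id,
               orthogroup_id = membership$orthogroup_id,
               stratum = as.integer(stratum),
               gain_node_label = ifelse(is.na(membership$orthogroup_id),
                   "focal-specific", st@strataLabels[stratum]),
               stringsAsFactors = FALSE)
}

#' Stratum composition of a gene-age table
#'
#' @param ages data.frame from [assignAges()] (needs a `stratum` column).
#' @param nStrata total stratum count S; strata with no genes are reported
#'   with count 0. Defaults to `max(ages$stratum)`.
#' @return data.frame with `stratum`, `count` and `fraction`; counts sum to
#'   the number of genes and fractions to 1.
#' @export
stratumComposition <- function(ages, nStrata = max(ages$stratum)) {
    if (nrow(ages) == 0L)
        stop("empty gene-age table")
    cnt <- tabulate(ages$stratum, nbins = nStrata)
    data.frame(stratum = seq_len(nStrata),
               count = cnt,
               fraction = cnt / sum(cnt))
}
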