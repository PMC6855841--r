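#' Build a ladderized species tree with a fixed number of phylostrata
#'
#' Constructs a rooted tree whose root-to-focal chain has exactly
#' `nStrata` nodes: each of the `nStrata - 1` internal chain nodes sprouts
#' a clade of outgroup species, and the focal leaf closes the chain. This
#' mirrors the shape used for phylostratigraphy of a focal proteome against
#' a ladder of increasingly close outgroups.
#'
#' @param nStrata number of strata S (>= 2).
#' @param outgroupSizes integer vector of length `nStrata - 1`: how many
#'   outgroup species branch off at each chain node, oldest first. The
#'   default spreads ~30 species over a 10-stratum chain.
#' @param focal focal leaf name.
#' @return a [SpeciesTree-class].
#' @examples
#' st <- simulateSpeciesTree(10)
#' nStrata(st)                   # 10
#' ape::Ntip(st@tree)            # 31 species
#' @export
simulateSpeciesTree <- function(nStrata = 10,
                                outgroupSizes = NULL,
                                focal = "focal") {
    if (nStrata < 2)
        stop("need at least 2 strata (root and focal leaf)")
    if (is.null(outgroupSizes)) {
        outgroupSizes <- rep(30L %/% (nStrata - 1L), nStrata - 1L)
        rem <- 30L - sum(outgroupSizes)
        if (rem > 0) outgroupSizes[seq_len(rem)] <-
            outgroupSizes[seq_len(rem)] + 1L
    }
    if (length(outgroupSizes) != nStrata - 1L || any(outgroupSizes < 1L))
        stop("outgroupSizes must have ", nStrata - 1L, " positive entries")
    clade <- function(k) {
        sp <- paste0("s", k, "_o", seq_len(outgroupSizes[k]))
        if (length(sp) == 1L) sp else
            paste0("(", paste(sp, collapse = ","), ")")
    }
    nwk <- focal
    for (k in rev(seq_len(nStrata - 1L)))
        nwk <- paste0("(", clade(k), ",", nwk, ")")
    phy <- ape::read.tree(text = paste0(nwk, ";"))
    speciesTree(phy, focal)
}

#' Simulate orthogroup phyletic patterns under a Dollo gain/loss model
#'
#' Each orthogroup is gained exactly once, at the chain node of a stratum
#' drawn from `gainWeights`; every branch strictly below the gain node then
#' loses the orthogroup independently with probability `lossProb`, losses
#' being inherited by whole subtrees. Presence in the focal species is
#' forced: branches on the gain-node-to-focal path never lose. The returned
#' truth table records each orthogroup's gain node and stratum, giving
#' downstream age inference a known answer.
#'
#' @param st a [SpeciesTree-class].
#' @param nGenes number of orthogroups to simulate.
#' @param gainWeights probability vector over strata 1..S (sums to 1);
#'   default uniform.
#' @param lossProb per-branch loss probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `phyletic` (a [PhyleticMatrix-class]) and `truth`
#'   (data.frame: `orthogroup_id`, `true_stratum`, `gain_node_label`).
#' @export
simulateDolloMatrix <- function(st, nGenes,
                                gainWeights = NULL,
                                lossProb = 0.1,
                                seed = 1L) {
    S <- nStrata(st)
    if (is.null(gainWeights)) gainWeights <- rep(1 / S, S)
    if (length(gainWeights) != S)
        stop("gainWeights must have one entry per stratum (", S, ")")
    if (abs(sum(gainWeights) - 1) > 1e-8)
        stop("gainWeights must sum to 1")
    if (lossProb < 0 || lossProb >= 1)
        stop("lossProb must lie in [0, 1)")
    phy <- st@tree
    ntip <- ape::Ntip(phy)
    kids <- childrenList(phy)
    onFocalPath <- logical(ntip + phy$Nnode)
    onFocalPath[st@strataNodes] <- TRUE

    withSeed(seed, {
        strata <- sample.int(S, nGenes, replace = TRUE, prob = gainWeights)
        m <- matrix(0L, nGenes, ntip,
                    dimnames = list(sprintf("OG%05d", seq_len(nGenes)),
                                    phy$tip.label))
        for (g in seq_len(nGenes)) {
            gain <- st@strataNodes[strata[g]]
            # iterative descent; a lost branch prunes its whole subtree
            stack <- gain
            while (length(stack)) {
                v <- stack[[length(stack)]]
                stack <- stack[-length(stack)]
                if (v <= ntip) {
                    m[g, v] <- 1L
                } else {
                    for (ch in kids[[v]]) {
                        lost <- !onFocalPath[ch] &&
                            stats::runif(1L) < lossProb
                        if (!lost) stack <- c(stack, ch)
                    }
                }
            }
        }
        list(phyletic = phyleticMatrix(m, st),
             truth = data.frame(orthogroup_id = rownames(m),
                                true_stratum = strata,
                                gain_node_label = st@strataLabels[strata],
                                stringsAsFactors = FALSE))
    })
}
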