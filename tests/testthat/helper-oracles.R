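# Independent oracles and small fixtures, built in code.

toyTree5 <- function() {
    speciesTree(ape::read.tree(text = "((((F,A),B),C),D);"), "F")
}

toyTree6 <- function() {
    speciesTree(ape::read.tree(text = "((((F,A),B),(C,D)),E);"), "F")
}

# Exhaustive single-gain Dollo oracle: for every candidate gain node whose
# subtree covers the present set, count the losses (maximal absent
# subtrees) a single-gain reconstruction needs, and return the node(s)
# with minimal loss count. Independent of the package's LCA shortcut.
oracleDolloGain <- function(st, present) {
    phy <- st@tree
    ntip <- ape::Ntip(phy)
    nnode <- ntip + phy$Nnode
    kids <- vector("list", nnode)
    for (i in seq_len(nrow(phy$edge)))
        kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
    presTip <- phy$tip.label %in% present
    hasPresent <- function(v) {
        if (v <= ntip) return(presTip[v])
        any(vapply(kids[[v]], hasPresent, TRUE))
    }
    lossCount <- function(v) {
        if (v <= ntip) return(0L)
        sum(vapply(kids[[v]], function(ch)
            if (!hasPresent(ch)) 1L else lossCount(ch), 0L))
    }
    leavesUnder <- function(v) {
        if (v <= ntip) return(phy$tip.label[v])
        unlist(lapply(kids[[v]], leavesUnder))
    }
    cand <- which(vapply(seq_len(nnode),
        function(v) all(present %in% leavesUnder(v)), TRUE))
    losses <- vapply(cand, lossCount, 0L)
    list(best = cand[losses == min(losses)],
         candidates = cand, losses = losses)
}

# All focal-containing presence patterns of a species tree.
allFocalPatterns <- function(st) {
    others <- setdiff(st@tree$tip.label, focalSpecies(st))
    patterns <- list()
    for (k in 0:length(others)) {
        sets <- utils::combn(others, k, simplify = FALSE)
        for (s in sets)
            patterns[[length(patterns) + 1L]] <- c(focalSpecies(st), s)
    }
    patterns
}

# Full hypergeometric enumeration of a 2x2 table with fixed margins,
# using binomial coefficients directly.
oracleFisher <- function(a, b, c, d) {
    r1 <- a + b; n <- a + b + c + d; c1 <- a + c
    xs <- max(0L, c1 - (n - r1)):min(r1, c1)
    p <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
    pa <- p[xs == a]
    list(pOne = sum(p[xs >= a]),
         pTwo = sum(p[p <= pa * (1 + 1e-7)]))
}

twoGeneExpr <- function(e1, e2) {
    m <- rbind(g1 = rep(e1, 2), g2 = rep(e2, 2))
    makeExprFixture(m, nT = 2)
}

# Small deterministic expression fixture: nGenes x (nT x nReps) tpm.
# Existing sample colnames are kept; otherwise t<hours>_r<rep> is used.
makeExprFixture <- function(tpmMatrix, nT = NULL, reps = NULL, tps = NULL) {
    n <- ncol(tpmMatrix)
    if (is.null(nT)) nT <- n
    if (is.null(reps)) reps <- rep(1L, n)
    if (is.null(tps))
        tps <- rep(seq(12, by = 6, length.out = nT), length.out = n)
    if (is.null(colnames(tpmMatrix)))
        colnames(tpmMatrix) <- sprintf("t%02d_r%d", tps, reps)
    if (is.null(rownames(tpmMatrix)))
        rownames(tpmMatrix) <- sprintf("g%03d", seq_len(nrow(tpmMatrix)))
    timecourseExperiment(tpmMatrix, timepoint = tps, replicate = reps)
}
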