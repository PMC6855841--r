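#' Sharply-activated temporal cluster profiles
#'
#' Unit-scale (max 1) profiles, one per cluster, each a sharp activation
#' bump centred at a different timepoint, emulating sequential waves of
#' transcriptional activation across a developmental time course.
#'
#' @param nTimepoints number of timepoints.
#' @param nClusters number of profiles.
#' @return numeric matrix, `nClusters` x `nTimepoints`, values in (0, 1].
#' @export
defaultClusterProfiles <- function(nTimepoints, nClusters = 5) {
    centers <- seq(1.5, nTimepoints - 0.5, length.out = nClusters)
    t <- seq_len(nTimepoints)
    prof <- t(vapply(centers,
        function(c0) 0.05 + 0.95 * exp(-0.5 * ((t - c0) / 1.0)^2),
        numeric(nTimepoints)))
    rownames(prof) <- paste0("cluster", seq_len(nClusters))
    prof
}

#' Simulate a replicated time-course expression dataset
#'
#' Generates a genes-by-samples tpm matrix with planted co-expression
#' clusters, a large low-expression fraction, multiplicative log-normal
#' noise, an optional replicate-2 program shift, and a tunable
#' age-by-phase interaction that produces hourglass (or inverse) TAI
#' profiles. For a clustered gene i at timepoint t the mean is
#' `base_i * profile_c(t) * (1 + delta * w(age_i) * m(t))`, where `m(t)`
#' is 1 on mid-phase timepoints and 0 elsewhere and `w` maps the oldest
#' stratum to +1 and the youngest to -1 linearly; observed tpm is the mean
#' times `exp(N(0, noiseSigma^2))`. With `hourglassDelta > 0` old genes
#' are boosted and young genes damped in mid-phase, so the
#' expression-weighted transcriptome age dips there (the hourglass);
#' a negative delta plants the inverse pattern; 0 gives a flat null.
#'
#' @param ages gene-age table ([assignAges()] output or the simulator
#'   truth): columns `gene_id` and `stratum`.
#' @param nTimepoints,nReplicates time-course dimensions.
#' @param timeStart,timeInterval timepoint labels in hours
#'   (`timeStart + (0:(nTimepoints-1)) * timeInterval`).
#' @param clusterProfiles profiles matrix (clusters x timepoints, unit
#'   scale); default [defaultClusterProfiles()].
#' @param clusterSizes member count per cluster; default 6% of genes each.
#' @param fracLow fraction of genes given baseline expression with
#'   expected mean below 0.5 tpm.
#' @param noiseSigma log-scale standard deviation of measurement noise.
#' @param hourglassDelta signed age-by-mid-phase effect size; means that
#'   would go negative are clipped at 0 with a warning.
#' @param midPhase timepoint indices forming the mid phase (default
#'   `3:6`, clipped to the observed range).
#' @param replicateShift integer number of timepoint slots by which the
#'   replicate-2 program lags replicate 1 (0 = synchronous).
#' @param ageBiasedClusters when TRUE the last (latest-activated) cluster
#'   is drawn preferentially from the youngest strata and the mid-course
#'   cluster from the oldest, planting an age-by-cluster enrichment whose
#'   shape (young late, old mid) is consistent with an hourglass TAI
#'   profile.
#' @param seed RNG seed; the whole draw is deterministic given it.
#' @return list with `expr` (a [TimecourseExperiment-class]), `truth`
#'   (data.frame: `gene_id`, `true_cluster` with NA for unclustered genes,
#'   `low_expressed`), `profiles`, and `patternKind` ("hourglass", "flat"
#'   or "inverse").
#' @export
simulateExpression <- function(ages,
                               nTimepoints = 10,
                               nReplicates = 2,
                               timeStart = 12,
                               timeInterval = 6,
                               clusterProfiles = NULL,
                               clusterSizes = NULL,
                               fracLow = 0.58,
                               noiseSigma = 0.25,
                               hourglassDelta = 0,
                               midPhase = 3:6,
                               replicateShift = 0,
                               ageBiasedClusters = FALSE,
                               seed = 1L) {
    n <- nrow(ages)
    S <- max(ages$stratum)
    if (is.null(clusterProfiles))
        clusterProfiles <- defaultClusterProfiles(nTimepoints)
    if (ncol(clusterProfiles) != nTimepoints)
        stop("clusterProfiles must have one column per timepoint")
    nClusters <- nrow(clusterProfiles)
    if (is.null(clusterSizes))
        clusterSizes <- rep(max(1L, floor(0.06 * n)), nClusters)
    if (length(clusterSizes) != nClusters)
        stop("need one cluster size per profile")
    midPhase <- intersect(midPhase, seq_len(nTimepoints))
    w <- if (S > 1) 1 - 2 * (ages$stratum - 1) / (S - 1) else rep(0, n)

    withSeed(seed, {
        lowIdx <- sample.int(n, round(fracLow * n))
        expressed <- setdiff(seq_len(n), lowIdx)
        if (sum(clusterSizes) > length(expressed))
            stop("sum(clusterSizes) exceeds the number of expressed genes")
        cluster <- rep(NA_integer_, n)
        pool <- expressed
        midCluster <- as.integer(ceiling(nClusters / 2))
        pickOrder <- c(nClusters, midCluster,
                       setdiff(seq_len(nClusters), c(midCluster, nClusters)))
        for (cc in pickOrder) {
            wts <- if (!ageBiasedClusters) rep(1, length(pool))
                else if (cc == nClusters) (ages$stratum[pool] / S)^4
                else if (cc == midCluster)
                    ((S + 1 - ages$stratum[pool]) / S)^4
                else rep(1, length(pool))
            pick <- sample(pool, clusterSizes[cc], prob = wts)
            cluster[pick] <- cc
            pool <- setdiff(pool, pick)
        }
        base <- numeric(n)
        base[expressed] <- stats::rlnorm(length(expressed),
                                         meanlog = log(20), sdlog = 1)
        base[lowIdx] <- stats::rlnorm(length(lowIdx),
                                      meanlog = log(0.08), sdlog = 0.5)
        prof <- matrix(1, n, nTimepoints)
        cl <- which(!is.na(cluster))
        prof[cl, ] <- clusterProfiles[cluster[cl], , drop = FALSE]

        mid <- as.numeric(seq_len(nTimepoints) %in% midPhase)
        hours <- timeStart + (seq_len(nTimepoints) - 1L) * timeInterval
        mats <- vector("list", nReplicates)
        clipped <- FALSE
        for (r in seq_len(nReplicates)) {
            tIdx <- seq_len(nTimepoints)
            if (r > 1L && replicateShift != 0)
                tIdx <- pmin(pmax(tIdx - replicateShift, 1L), nTimepoints)
            mu <- base * prof[, tIdx, drop = FALSE] *
                (1 + hourglassDelta * outer(w, mid))
            if (any(mu < 0)) {
                clipped <- TRUE
                mu[mu < 0] <- 0
            }
            obs <- mu * exp(matrix(stats::rnorm(n * nTimepoints,
                                                sd = noiseSigma),
                                   n, nTimepoints))
            colnames(obs) <- sprintf("t%02d_r%d", hours, r)
            mats[[r]] <- obs
        }
        if (clipped)
            warning("hourglassDelta drove some means negative; clipped at 0")
        m <- do.call(cbind, mats)
        rownames(m) <- ages$gene_id
        expr <- timecourseExperiment(m,
            timepoint = rep(hours, nReplicates),
            replicate = rep(seq_len(nReplicates), each = nTimepoints))
        list(expr = expr,
             truth = data.frame(gene_id = ages$gene_id,
                                true_cluster = cluster,
                                low_expressed = seq_len(n) %in% lowIdx,
                                stringsAsFactors = FALSE),
             profiles = clusterProfiles,
             patternKind = if (hourglassDelta > 0) "hourglass"
                           else if (hourglassDelta < 0) "inverse"
                           else "flat")
    })
}

#' Simulate a complete study dataset with known ground truth
#'
#' Chains the two simulators: builds the ladderized species tree, draws
#' orthogroup phyletic patterns under the Dollo gain/loss model, derives a
#' gene-to-orthogroup membership table (a fraction of genes are orphans
#' with no orthogroup, hence focal-specific), and simulates the expression
#' time course from the true gene ages.
#'
#' @param seed RNG seed driving all draws.
#' @param nGenes number of focal-species genes.
#' @param nStrata number of phylostrata.
#' @param lossProb per-branch Dollo loss probability.
#' @param fracOrphan fraction of genes with no orthogroup anywhere.
#' @param ... further arguments passed to [simulateExpression()].
#' @return list with `tree`, `phyletic`, `membership`, `trueAges`,
#'   `expr`, `truth` (expression truth), and `dolloTruth`.
#' @export
simulateStudyDataset <- function(seed = 1L, nGenes = 2000, nStrata = 10,
                                 lossProb = 0.1, fracOrphan = 0.15, ...) {
    st <- simulateSpeciesTree(nStrata)
    nOrphan <- round(fracOrphan * nGenes)
    nOg <- nGenes - nOrphan
    dollo <- simulateDolloMatrix(st, nOg, lossProb = lossProb, seed = seed)
    membership <- data.frame(
        gene_id = sprintf("g%05d", seq_len(nGenes)),
        orthogroup_id = c(orthogroupIds(dollo$phyletic),
                          rep(NA_character_, nOrphan)),
        stringsAsFactors = FALSE)
    trueAges <- data.frame(
        gene_id = membership$gene_id,
        stratum = c(dollo$truth$true_stratum,
                    rep(nStrata, nOrphan)),
        stringsAsFactors = FALSE)
    sim <- simulateExpression(trueAges, seed = seed + 1L, ...)
    list(tree = st, phyletic = dollo$phyletic, membership = membership,
         trueAges = trueAges, expr = sim$expr, truth = sim$truth,
         dolloTruth = dollo$truth, patternKind = sim$patternKind)
}
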