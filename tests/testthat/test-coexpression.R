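makeNorm <- function(m, nT, reps) normalizeExpression(
    makeExprFixture(m, nT = nT, reps = reps))

test_that("two noiseless orthogonal programs are recovered perfectly", {
    profA <- c(10, 8, 6, 4, 2, 1)
    profB <- rev(profA)
    m <- rbind(t(replicate(50, profA)), t(replicate(50, profB)))
    rownames(m) <- sprintf("g%03d", 1:100)
    norm <- makeNorm(m, nT = 6, reps = rep(1L, 6))
    cl <- consensusCluster(norm, kGrid = 2:4, nBaseRuns = 5, seed = 2)
    expect_equal(cl$nClusters, 2L)
    expect_equal(sort(cl$sizes), c(50L, 50L))
    expect_equal(sum(is.na(cl$assignment$cluster)), 0L)
    got <- cl$assignment$cluster
    expect_equal(length(unique(got[1:50])), 1L)
    expect_equal(length(unique(got[51:100])), 1L)
    expect_false(got[1] == got[51])
})

test_that("clustering is deterministic and validates its inputs", {
    set.seed(3)
    m <- matrix(rlnorm(60 * 6), 60, 6,
                dimnames = list(sprintf("g%02d", 1:60), NULL))
    norm <- makeNorm(m, nT = 6, reps = rep(1L, 6))
    a <- consensusCluster(norm, kGrid = 3:5, nBaseRuns = 5, seed = 4)
    b <- consensusCluster(norm, kGrid = 3:5, nBaseRuns = 5, seed = 4)
    expect_identical(a$assignment, b$assignment)
    expect_error(consensusCluster(norm, kGrid = c(3, 60), seed = 1),
                 "k >= number of genes")
})

test_that("planted clusters are found and unstructured genes left out", {
    ages <- data.frame(gene_id = sprintf("g%04d", 1:350),
                       stratum = rep(1:10, 35))
    sim <- simulateExpression(ages, clusterSizes = rep(50, 5), fracLow = 0,
                              noiseSigma = 0.2, seed = 6)
    norm <- normalizeExpression(sim$expr)
    cl <- consensusCluster(norm, kGrid = 5:12, nBaseRuns = 10, seed = 8)
    a <- cl$assignment
    truthLab <- ifelse(is.na(sim$truth$true_cluster), 0L,
                       sim$truth$true_cluster)
    asg <- !is.na(a$cluster)
    expect_gte(mclust::adjustedRandIndex(a$cluster[asg], truthLab[asg]), 0.9)
    noise <- is.na(sim$truth$true_cluster)
    expect_gt(mean(is.na(a$cluster[noise])), 0.5)
    # no extracted cluster smaller than the minimum size
    expect_true(all(cl$sizes >= 10))
})

test_that("raising the consensus threshold never assigns more genes", {
    ages <- data.frame(gene_id = sprintf("g%04d", 1:300),
                       stratum = rep(1:10, 30))
    sim <- simulateExpression(ages, clusterSizes = rep(40, 5), fracLow = 0,
                              noiseSigma = 0.3, seed = 15)
    norm <- normalizeExpression(sim$expr)
    assigned <- vapply(c(0.5, 0.7, 0.9), function(tau) {
        cl <- consensusCluster(norm, kGrid = 5:10, nBaseRuns = 8,
                               tau = tau, seed = 5)
        sum(!is.na(cl$assignment$cluster))
    }, 0)
    expect_true(all(diff(assigned) <= 0))
})

test_that("cluster membership is robust across replicates", {
    ages <- data.frame(gene_id = sprintf("g%04d", 1:300),
                       stratum = rep(1:10, 30))
    sim <- simulateExpression(ages, clusterSizes = rep(50, 5), fracLow = 0,
                              noiseSigma = 0.2, seed = 19)
    rr <- replicateRobustness(sim$expr, kGrid = 5:10, nBaseRuns = 10,
                              seed = 23)
    expect_equal(nrow(rr), 3L)
    expect_true(all(rr$ari >= 0.8))

    # identical replicates agree perfectly
    m1 <- tpm(sim$expr)[, sampleReplicates(sim$expr) == 1]
    mm <- cbind(m1, m1)
    colnames(mm) <- NULL
    dup <- makeExprFixture(mm, nT = 10, reps = rep(1:2, each = 10))
    rrDup <- replicateRobustness(dup, kGrid = 5:10, nBaseRuns = 10,
                                 seed = 23)
    expect_equal(rrDup$ari[rrDup$run1 == "replicate1" &
                           rrDup$run2 == "replicate2"], 1)

    # independent random data carry no reproducible cluster signal
    set.seed(41)
    rnd <- matrix(rlnorm(300 * 20, 2, 1), 300, 20,
                  dimnames = list(sprintf("g%04d", 1:300), NULL))
    rndX <- makeExprFixture(rnd, nT = 10, reps = rep(1:2, each = 10))
    rrRnd <- replicateRobustness(rndX, kGrid = 5:10, nBaseRuns = 10,
                                 seed = 29)
    # the two replicates are independent, so their agreement is at chance;
    # the averaged run shares data with each replicate and is not assessed
    indep <- rrRnd[rrRnd$run1 == "replicate1" & rrRnd$run2 == "replicate2", ]
    expect_true(is.na(indep$ari) || abs(indep$ari) < 0.2)
    expect_lt(indep$nShared / 300, 0.3)
})

test_that("cluster profiles summarize member means and dispersions", {
    # g2's log2 profile is the exact mirror of g1's, so their normalized
    # profiles are p and -p
    m <- rbind(g1 = c(1, 3, 1, 3), g2 = c(3, 1, 3, 1), g3 = c(1, 5, 1, 5))
    norm <- makeNorm(m, nT = 4, reps = rep(1L, 4))
    z <- SummarizedExperiment::assay(norm, "normalized")
    # single-member cluster: profile equals the member
    asg <- data.frame(gene_id = c("g1", "g2", "g3"),
                      cluster = c(1L, NA, NA))
    pr <- meanClusterProfiles(norm, asg)
    expect_equal(pr$mean, unname(z["g1", ]))
    expect_equal(pr$sd, rep(NA_real_, 4))
    # opposite members average to zero
    asg2 <- data.frame(gene_id = c("g1", "g2", "g3"),
                       cluster = c(1L, 1L, NA))
    pr2 <- meanClusterProfiles(norm, asg2)
    expect_true(all(abs(pr2$mean) < 1e-12))
})

test_that("noiseless planted profiles are recovered as cluster means", {
    profs <- defaultClusterProfiles(8, 3)
    m <- profs[rep(1:3, each = 15), ] * 40   # equal base within clusters
    rownames(m) <- sprintf("g%03d", 1:45)
    norm <- makeNorm(m, nT = 8, reps = rep(1L, 8))
    z <- SummarizedExperiment::assay(norm, "normalized")
    asg <- data.frame(gene_id = rownames(z),
                      cluster = rep(1:3, each = 15))
    pr <- meanClusterProfiles(norm, asg)
    # identical members: the mean equals any member, dispersion vanishes
    expect_true(all(pr$sd < 1e-9))
    for (cc in 1:3)
        expect_equal(pr$mean[pr$cluster == cc],
                     unname(z[which(asg$cluster == cc)[1], ]))
})
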