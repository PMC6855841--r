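test_that("fisher2x2 handles boundary tables exactly", {
    r <- fisher2x2(0, 10, 0, 10)
    expect_equal(r$p_one, 1)
    expect_equal(r$p_two, 1)
    perfect <- fisher2x2(10, 0, 0, 10)
    expect_equal(perfect$p_two, 2 / choose(20, 10))
    expect_equal(perfect$p_one, 1 / choose(20, 10))
    expect_true(is.infinite(perfect$odds_ratio))
    expect_true(is.nan(fisher2x2(0, 0, 0, 5)$odds_ratio))
    expect_equal(fisher2x2(2, 3, 4, 5)$odds_ratio, (2 * 5) / (3 * 4))
    expect_error(fisher2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher2x2 matches full hypergeometric enumeration", {
    # dense small grid plus random larger-margin tables
    for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
        if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
        r <- fisher2x2(a, b, c, d)
        o <- oracleFisher(a, b, c, d)
        expect_lt(abs(r$p_one - o$pOne), 1e-12)
        expect_lt(abs(r$p_two - o$pTwo), 1e-12)
    }
    set.seed(6)
    for (i in 1:100) {
        cells <- rmultinom(1, sample(20:120, 1), runif(4, 0.05, 1))[, 1]
        r <- fisher2x2(cells[1], cells[2], cells[3], cells[4])
        o <- oracleFisher(cells[1], cells[2], cells[3], cells[4])
        expect_lt(abs(r$p_one - o$pOne), 1e-12)
        expect_lt(abs(r$p_two - o$pTwo), 1e-12)
    }
})

test_that("fisher p-values are invariant to transposition and row/col swaps", {
    set.seed(8)
    for (i in 1:20) {
        cells <- sample(0:30, 4, replace = TRUE)
        if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
            cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
        a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
        r <- fisher2x2(a, b, c, d)
        tr <- fisher2x2(a, c, b, d)                 # transpose
        sw <- fisher2x2(d, c, b, a)                 # swap rows and columns
        expect_equal(tr$p_two, r$p_two, tolerance = 1e-12)
        expect_equal(sw$p_two, r$p_two, tolerance = 1e-12)
        expect_equal(sw$p_one, r$p_one, tolerance = 1e-12)
    }
})

test_that("the conserved-lincRNA style table reproduces the enumeration oracle", {
    r <- fisher2x2(5, 19, 65, 926)
    o <- oracleFisher(5, 19, 65, 926)
    expect_lt(abs(r$p_one - o$pOne), 1e-12)
    expect_lt(abs(r$p_two - o$pTwo), 1e-12)
    # same table built from gene sets
    universe <- sprintf("g%04d", 1:1015)
    setA <- universe[1:24]                       # conserved lincRNAs
    setB <- c(universe[1:5], universe[25:89])    # clustered transcripts
    s <- setOverlapEnrichment(setA, setB, universe)
    expect_equal(s[, c("a", "b", "c", "d")],
                 r[, c("a", "b", "c", "d")])
    expect_equal(s$p_two, r$p_two)
})

test_that("set-overlap enrichment handles identity and disjoint cases", {
    u <- sprintf("g%03d", 1:100)
    expect_equal(setOverlapEnrichment(u, u, u)$p_one, 1)
    expect_equal(setOverlapEnrichment(u[1:10], u[11:30], u)$p_one, 1,
                 tolerance = 1e-6)
    expect_error(setOverlapEnrichment(c(u[1], "zz"), u[1:5], u), "subset")
})

test_that("a fully concentrated stratum gives the extreme enrichment p", {
    n <- 40; k <- 8
    ages <- data.frame(gene_id = sprintf("g%03d", 1:n),
                       stratum = c(rep(10L, k), rep(1L, n - k)))
    asg <- data.frame(gene_id = ages$gene_id,
                      cluster = c(rep(1L, k), rep(NA_integer_, n - k)))
    en <- stratumClusterEnrichment(ages, asg, adjust = FALSE)
    row <- en[en$cluster == 1 & en$stratum == 10, ]
    expect_equal(row$p_one, 1 / choose(n, k))
})

test_that("independent ages and clusters yield few adjusted discoveries", {
    set.seed(27)
    n <- 2000
    ages <- data.frame(gene_id = sprintf("g%04d", 1:n),
                       stratum = sample.int(10, n, replace = TRUE))
    asg <- data.frame(gene_id = ages$gene_id,
                      cluster = sample(c(1:6, NA), n, replace = TRUE))
    en <- stratumClusterEnrichment(ages, asg)
    expect_lte(mean(en$p_adj < 0.05), 0.05)
    # BH never lowers a p-value and preserves order
    expect_true(all(en$p_adj >= en$p_one - 1e-15))
    ord <- order(en$p_one)
    expect_true(all(diff(en$p_adj[ord]) >= -1e-15))
})

test_that("a planted young-biased cluster is the top enrichment hit", {
    ages <- data.frame(gene_id = sprintf("g%04d", 1:800),
                       stratum = rep(1:10, 80))
    sim <- simulateExpression(ages, clusterSizes = rep(60, 5),
                              fracLow = 0.2, noiseSigma = 0.2,
                              ageBiasedClusters = TRUE, seed = 44)
    asg <- data.frame(gene_id = sim$truth$gene_id,
                      cluster = sim$truth$true_cluster)
    en <- stratumClusterEnrichment(ages, asg)
    # both planted biases surface: young genes in the late cluster (5) and
    # old genes in the mid cluster (3); the late/young pair must dominate
    # all young-stratum pairs and be a clear discovery
    young <- en[en$stratum == 10, ]
    expect_equal(young$cluster[which.min(young$p_adj)], 5)
    expect_lt(en$p_adj[en$cluster == 5 & en$stratum == 10], 1e-4)
    top <- en[which.min(en$p_adj), ]
    expect_true((top$cluster == 5 && top$stratum >= 9) ||
                (top$cluster == 3 && top$stratum <= 2))
})
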