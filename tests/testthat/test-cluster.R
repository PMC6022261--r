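test_that("hierarchical clustering recovers planted well-separated groups", {
    # two tight pairs far apart; brute force over all 2-partitions
    # minimizing the maximum within-cluster distance gives {1,2} {3,4}
    x <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(5, 5), d = c(5.1, 5))
    d <- pairwiseDistances(methFixture(x, scale = "mvalue"),
                           WeightingScheme("none"))
    cl <- hierarchicalCluster(d, k = 2)
    expect_true(exactMatch(clusterLabels(cl), c(1, 1, 2, 2)))
    # degenerate cuts
    expect_equal(length(unique(clusterLabels(hierarchicalCluster(d, 4)))), 4)
    expect_equal(length(unique(clusterLabels(hierarchicalCluster(d, 1)))), 1)
    expect_error(hierarchicalCluster(d, 5), "k")
})

test_that("complete linkage is invariant to monotone rescaling", {
    set.seed(8)
    x <- matrix(rnorm(60), 20, 3)
    m <- methFixture(x, scale = "mvalue")
    d1 <- pairwiseDistances(m, WeightingScheme("none"))
    d2 <- d1; d2@mat <- d2@mat * 3.7
    l1 <- clusterLabels(hierarchicalCluster(d1, 4))
    l2 <- clusterLabels(hierarchicalCluster(d2, 4))
    expect_true(exactMatch(l1, l2))
})

test_that("exact match is relabel-invariant and strict", {
    expect_true(exactMatch(c("A", "A", "A", "B", "B", "B"),
                           c(2, 2, 2, 1, 1, 1)))
    expect_true(exactMatch(1:5, 1:5))
    expect_false(exactMatch(c(1, 1, 2, 2, 2, 2), c(1, 1, 1, 2, 2, 2)))
    expect_error(exactMatch(1:3, 1:4), "length")
})

test_that("adjusted Rand index behaves as the chance-corrected agreement", {
    expect_equal(adjustedRand(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
    expect_equal(adjustedRand(rep(1, 6), c(1, 1, 1, 2, 2, 2)), 0)
    # 6 items, 3+3 truth, one item misassigned: closed form from the
    # contingency table [[2,0],[1,3]] -> ARI = (3+3+1-sum) scaled
    pred <- c(1, 1, 2, 2, 2, 2); truth <- c(1, 1, 1, 2, 2, 2)
    idx <- choose(2, 2) + choose(1, 2) + choose(3, 2) # sum nij C2 = 4
    a <- choose(2, 2) + choose(4, 2); b <- choose(3, 2) + choose(3, 2)
    exp_idx <- a * b / choose(6, 2)
    want <- (4 - exp_idx) / ((a + b) / 2 - exp_idx)
    expect_equal(adjustedRand(pred, truth), want)
})

test_that("exact match coincides with ARI reaching one", {
    set.seed(12)
    for (i in 1:40) {
        p <- sample(1:3, 8, replace = TRUE)
        t <- sample(1:3, 8, replace = TRUE)
        expect_equal(exactMatch(p, t),
                     isTRUE(all.equal(adjustedRand(p, t), 1)))
    }
})

test_that("bipartition count matches exhaustive enumeration", {
    enum <- function(n) {
        # label vectors over {1,2} with both groups non-empty, modulo swap
        labs <- as.matrix(expand.grid(rep(list(1:2), n)))
        keep <- apply(labs, 1, function(z) length(unique(z)) == 2)
        canon <- apply(labs[keep, , drop = FALSE], 1,
                       function(z) paste(match(z, unique(z)), collapse = ""))
        length(unique(canon))
    }
    for (n in 2:12) expect_equal(countBipartitions(n), enum(n))
    expect_equal(countBipartitions(6), 31)
    expect_error(countBipartitions(1), "at least 2")
    expect_equal(randomPartitionCorrectProb(6), 1 / 31)
    expect_equal(randomPartitionCorrectProb(2), 1)
    expect_equal(randomPartitionCorrectProb(4), 1 / 7)
})

test_that("silhouette mean matches the per-point hand computation", {
    # two pairs: within-pair distance 1, across-pair distance 3
    m <- matrix(3, 4, 4); diag(m) <- 0
    m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
    d <- new("DistanceMatrix", mat = m, metric = "euclidean",
             scheme = WeightingScheme("none"), axis = "sites")
    expect_equal(silhouetteMean(d, c(1, 1, 2, 2)), 2 / 3)
    # perfectly tight clusters: a = 0, b > 0 -> silhouette 1
    m0 <- matrix(3, 4, 4); diag(m0) <- 0
    m0[1, 2] <- m0[2, 1] <- 0; m0[3, 4] <- m0[4, 3] <- 0
    d0 <- new("DistanceMatrix", mat = m0, metric = "euclidean",
              scheme = WeightingScheme("none"), axis = "sites")
    expect_equal(silhouetteMean(d0, c(1, 1, 2, 2)), 1)
    expect_error(silhouetteMean(d, rep(1, 4)), "2 clusters")
})

test_that("benchmark returns 1 in the separable limit and is seeded", {
    easy <- benchmarkSuite(1:10, effectSize = 0.9,
                           lowCoverageFraction = 0, muLog = log(2000),
                           sigmaLog = 0.1, jitterConcentration = 5000)
    expect_equal(benchmarkSampleClustering(easy), 1)
    suite <- benchmarkSuite(1:25)
    accNone <- benchmarkSampleClustering(suite, WeightingScheme("none"))
    accA0 <- benchmarkSampleClustering(suite,
        WeightingScheme("threshold", alphaQuantile = 0, beta = 0.5))
    expect_identical(accNone, accA0) # reduction property
    expect_identical(benchmarkSampleClustering(suite, WeightingScheme("none")),
                     accNone)
    expect_error(benchmarkSampleClustering(list()), "empty")
})

test_that("grid search is reproducible and covers its grid", {
    g1 <- gridSearch(alphaGrid = c(0, 0.45), betaGrid = c(0.09, 1),
                     sizeGrid = c(10, 30), reps = 5, seed = 11)
    g2 <- gridSearch(alphaGrid = c(0, 0.45), betaGrid = c(0.09, 1),
                     sizeGrid = c(10, 30), reps = 5, seed = 11)
    expect_identical(g1, g2)
    expect_equal(nrow(g1), 8)
    expect_true(all(g1$accuracy >= 0 & g1$accuracy <= 1))
    # alpha = 0 and beta = 1 cells reduce to the same unweighted result
    sub <- g1[g1$n_sites == 30, ]
    expect_equal(unique(sub$accuracy[sub$alpha == 0 | sub$beta == 1]),
                 sub$accuracy[sub$alpha == 0 & sub$beta == 0.09])
    expect_error(gridSearch(alphaGrid = numeric(0)), "non-empty")
})
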