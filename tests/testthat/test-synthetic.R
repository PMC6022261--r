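test_that("simulated counts conserve totals and honor the seed", {
    sim <- simulateCounts(nSites = 50, nConditions = 4, nModules = 3,
                          seed = 7)
    t <- ipCounts(sim$counts); c <- inputCounts(sim$counts)
    expect_true(all(t >= 0) && all(c >= 0))
    expect_true(all(t == round(t)))
    expect_equal(dim(t), c(50, 4))
    expect_equal(unname(table(sim$truth$siteModules)), c(17, 17, 16),
                 ignore_attr = TRUE)
    sim2 <- simulateCounts(nSites = 50, nConditions = 4, nModules = 3,
                           seed = 7)
    expect_identical(ipCounts(sim$counts), ipCounts(sim2$counts))
    expect_identical(inputCounts(sim$counts), inputCounts(sim2$counts))
    sim3 <- simulateCounts(nSites = 50, nConditions = 4, nModules = 3,
                           seed = 8)
    expect_false(identical(ipCounts(sim$counts), ipCounts(sim3$counts)))
    expect_error(simulateCounts(nSites = 10, moduleSizes = c(3, 3)),
                 "sum")
})

test_that("estimated levels concentrate on the planted profiles at high coverage", {
    sim <- simulateCounts(nSites = 400, nConditions = 6, nModules = 4,
                          muLog = log(20000), sigmaLog = 0,
                          jitterConcentration = 1e6, seed = 13)
    t <- ipCounts(sim$counts); c <- inputCounts(sim$counts)
    mhat <- t / (t + c)
    pi <- sim$truth$profiles[sim$truth$siteModules, ]
    expect_gt(mean(abs(mhat - pi) <= 0.02), 0.99)
})

test_that("forcing universal low coverage degenerates to the midpoint", {
    sim <- simulateCounts(nSites = 80, nConditions = 4,
                          lowCoverageFraction = 1, lowLambda = 0.01,
                          backgroundRate = 0, seed = 5)
    cov <- siteCoverage(sim$counts)
    expect_gt(mean(cov == 0), 0.95)
    # too sparse for depth estimation; unit factors with a warning
    expect_warning(m <- computeMethylation(sim$counts), "unit factors")
    expect_gt(mean(methLevels(m) == 0.5), 0.9)
})

test_that("the benchmark generator matches the 6-sample two-group design", {
    ds <- makeSampleBenchmark(seed = 3)
    expect_equal(ncol(ds$counts), 6)
    expect_equal(nrow(ds$counts), 30)
    expect_equal(unname(table(ds$truth$sampleGroups)), c(3, 3),
                 ignore_attr = TRUE)
    expect_identical(ipCounts(makeSampleBenchmark(seed = 3)$counts),
                     ipCounts(ds$counts))
    expect_error(makeSampleBenchmark(effectSize = 0), "effectSize")
    expect_error(makeSampleBenchmark(effectSize = 1), "effectSize")
})

test_that("a vanishing group effect drops accuracy to the random floor", {
    suite <- benchmarkSuite(1:120, effectSize = 1e-4)
    acc <- benchmarkSampleClustering(suite, WeightingScheme("none"))
    # random-guess probability for 6 samples is 1/31; allow 3 binomial se
    p0 <- randomPartitionCorrectProb(6)
    expect_lt(acc, p0 + 3 * sqrt(p0 * (1 - p0) / 120) + 0.02)
})

test_that("synthetic annotation is seeded and plants its designated term", {
    genes <- paste0("g", 1:40)
    a1 <- makeAnnotation(genes, nTerms = 10, termSizeRange = c(3, 8),
                         plantedGenes = genes[1:5], seed = 2)
    a2 <- makeAnnotation(genes, nTerms = 10, termSizeRange = c(3, 8),
                         plantedGenes = genes[1:5], seed = 2)
    expect_identical(a1, a2)
    expect_setequal(a1$gene_id[a1$term_id == "TERM_planted"], genes[1:5])
    res <- moduleSignificance(genes[1:5], genes, a1)
    expect_equal(res$terms$term_id[1], "TERM_planted")
    expect_error(makeAnnotation(genes, termSizeRange = c(5, 100)),
                 "universe")
})

test_that("planted modules are recovered by the weighted pipeline", {
    # compact recovery check; the full-scale version runs in acceptance
    aris <- vapply(1:8, function(s) {
        sim <- simulateCounts(nSites = 300, nConditions = 9, nModules = 5,
                              muLog = log(300), sigmaLog = 0.5, seed = s)
        meth <- preprocessMethylation(sim$counts, nByMean = 300,
                                      nByVariance = 300)
        d <- pairwiseDistances(meth, WeightingScheme("threshold"))
        cl <- hierarchicalCluster(d, k = 5)
        adjustedRand(clusterLabels(cl), sim$truth$siteModules)
    }, numeric(1))
    expect_gt(mean(aris >= 0.9), 0.85)
})

test_that("low-coverage injection degrades clustering and weighting rescues it", {
    res <- vapply(1:30, function(s) {
        sim <- simulateCounts(nSites = 200, nConditions = 9, nModules = 5,
                              muLog = log(300), sigmaLog = 0.5,
                              lowCoverageFraction = 0.45, lowLambda = 2,
                              seed = s)
        meth <- preprocessMethylation(sim$counts, nByMean = 200,
                                      nByVariance = 200, constant = "zero")
        truth <- sim$truth$siteModules
        ariOf <- function(sch) {
            cl <- hierarchicalCluster(pairwiseDistances(meth, sch), k = 5)
            adjustedRand(clusterLabels(cl), truth)
        }
        c(none = ariOf(WeightingScheme("none")),
          thr = ariOf(WeightingScheme("threshold", 0.45, 0.09)))
    }, numeric(2))
    # degradation: corrupted data no longer clusters cleanly
    expect_lt(mean(res["none", ]), 0.9)
    # rescue: the threshold scheme recovers part of the loss
    wt <- wilcox.test(res["thr", ], res["none", ], paired = TRUE,
                      alternative = "greater")
    expect_lt(wt$p.value, 0.05)
})
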