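test_that("replicate merging sums counts per condition", {
    ip <- matrix(c(3L, 4L, 1L, 6L, 2L, 2L), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("r1", "r2", "r3")))
    input <- matrix(0L, 2, 3, dimnames = dimnames(ip))
    x <- MeripCountSet(ip, input, condition = c("A", "A", "B"))
    m <- mergeReplicates(x)
    expect_equal(ncol(m), 2)
    expect_equal(unname(ipCounts(m)[, "A"]), c(4, 10)) # c(3,1)+c(1,6)
    expect_equal(unname(ipCounts(m)[, "B"]), c(2, 2))

    # one replicate per condition: identity on the counts
    y <- MeripCountSet(ip, input, condition = c("A", "B", "C"))
    expect_equal(unname(ipCounts(mergeReplicates(y))), unname(ip))

    # unmapped replicate column is an error
    z <- MeripCountSet(ip, input, condition = c("A", NA, "B"))
    expect_error(mergeReplicates(z), "condition")
})

test_that("size factors are column totals normalized to mean one", {
    ip <- matrix(c(6e5, 4e5, 1.8e6, 1.2e6), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
    x <- MeripCountSet(ip, ip, condition = c("A", "B"))
    sf <- sizeFactors(estimateSizeFactors(x))
    expect_equal(unname(sf[, "ip"]), c(0.5, 1.5)) # totals 1e6, 3e6
    expect_equal(mean(sf[, "ip"]), 1)

    # equal depth gives unit factors
    y <- MeripCountSet(matrix(c(5e5, 5e5, 5e5, 5e5), 2, 2,
                              dimnames = dimnames(ip)),
                       ip, condition = c("A", "B"))
    expect_equal(unname(sizeFactors(estimateSizeFactors(y))[, "ip"]),
                 c(1, 1))

    # an all-zero column cannot be depth-normalized
    z <- MeripCountSet(matrix(c(1, 0, 2, 0), 2, 2,
                              dimnames = dimnames(ip)) * 0:1,
                       ip, condition = c("A", "B"))
    expect_error(estimateSizeFactors(z), "all-zero")
})

test_that("methylation level follows the size-factor-corrected IP fraction", {
    expect_equal(methylationLevel(100, 0), 1)
    expect_equal(methylationLevel(1, 0), 1)
    expect_equal(methylationLevel(0, 7, 2, 3), 0)
    expect_equal(methylationLevel(5, 5), 0.5)
    # reduces to t/(t+c) when factors are equal
    expect_equal(methylationLevel(3, 9, 2, 2), 3 / 12)
    # general factors: m = (t dC) / (t dC + c dT)
    expect_equal(methylationLevel(10, 10, 2, 1), 10 / 30)
    # zero coverage returns the uninformative midpoint
    expect_equal(methylationLevel(0, 0), 0.5)
    expect_error(methylationLevel(-1, 2), "non-negative")
    # monotone non-decreasing in t for fixed c
    m <- methylationLevel(0:50, 7)
    expect_true(all(diff(m) >= 0))
})

test_that("M-value is a sign-symmetric log ratio with additive offset", {
    expect_equal(mValue(8, 8), 0)
    expect_equal(mValue(4, 0, eps = 0.5), log2(9)) # 4.5 / 0.5
    expect_equal(mValue(3, 11, 1.2, 0.7), -mValue(11, 3, 0.7, 1.2))
    expect_error(mValue(1, 1, eps = 0), "eps")
})

test_that("quantile normalization equalizes sorted columns, with mean ties", {
    q <- methLevels(quantileNormalize(methFixture(
        cbind(a = c(1, 3), b = c(8, 2)) / 10, stage = "raw")))
    expect_equal(unname(q[, 1]), c(0.15, 0.55))
    expect_equal(unname(q[, 2]), c(0.55, 0.15))

    # identical columns are unchanged; sorted columns agree element-wise
    v <- matrix(runif(40), 10, 4)
    v[, 2:4] <- v[, 1]
    expect_equal(methLevels(quantileNormalize(methFixture(v, stage = "raw"))),
                 v, ignore_attr = TRUE)
    set.seed(7)
    v2 <- matrix(runif(60), 20, 3)
    q2 <- methLevels(quantileNormalize(methFixture(v2, stage = "raw")))
    expect_equal(unname(sort(q2[, 1])), unname(sort(q2[, 2])))
    expect_equal(unname(sort(q2[, 2])), unname(sort(q2[, 3])))
    # and within-column rank order is preserved
    expect_equal(order(q2[, 3]), order(v2[, 3]))
})

test_that("dynamic-site selection is two-stage with stable ties and order", {
    v <- rbind(s1 = c(0.9, 0.9, 0.9),   # high mean, zero variance
               s2 = c(0.1, 0.5, 0.9),   # mid mean, high variance
               s3 = c(0.45, 0.5, 0.55), # mid mean, low variance
               s4 = c(0.0, 0.1, 0.05))  # low mean
    m <- methFixture(v, stage = "raw")
    # stage 1 keeps s1..s3 by mean; stage 2 keeps s2 by variance
    out <- selectDynamicSites(m, nByMean = 3, nByVariance = 1)
    expect_equal(rownames(methLevels(out)), "s2")
    # permissive sizes retain everything in original order
    all <- selectDynamicSites(m, nByMean = 10, nByVariance = 10)
    expect_equal(rownames(methLevels(all)), rownames(v))
    expect_error(selectDynamicSites(m, nByMean = 0), "positive")
})

test_that("row standardization gives sample-sd z-scores and flags constants", {
    m <- methFixture(rbind(s1 = c(1, 2, 3)), scale = "mvalue", stage = "raw")
    z <- standardizeRows(m)
    expect_equal(unname(methLevels(z)[1, ]), c(-1, 0, 1))
    expect_equal(methStage(z), "standardized")
    # idempotent on already-standardized rows
    expect_equal(methLevels(standardizeRows(z)), methLevels(z))
    const <- methFixture(rbind(flat = c(0.4, 0.4, 0.4)), stage = "raw")
    expect_error(standardizeRows(const), "flat")
    expect_equal(unname(methLevels(standardizeRows(const,
                                                   constant = "zero"))[1, ]),
                 c(0, 0, 0))
})

test_that("standardized rows have mean zero and unit sample sd", {
    set.seed(11)
    m <- methFixture(matrix(runif(50), 10, 5), stage = "raw")
    z <- methLevels(standardizeRows(m))
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("the quantification pipeline is deterministic end to end", {
    sim <- simulateCounts(nSites = 60, nConditions = 4, nModules = 3,
                          seed = 42)
    a <- preprocessMethylation(sim$counts, nByMean = 50, nByVariance = 30)
    b <- preprocessMethylation(sim$counts, nByMean = 50, nByVariance = 30)
    expect_identical(methLevels(a), methLevels(b))
    expect_identical(methCoverage(a), methCoverage(b))
    expect_equal(nrow(methLevels(a)), 30)
    expect_equal(methStage(a), "standardized")
})
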