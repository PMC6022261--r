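# Small programmatic fixtures shared across test files.

# deterministic tiny count set: 4 sites x 2 samples
tinyCounts <- function() {
    ip <- matrix(c(10L, 0L, 5L, 3L,
                   2L, 7L, 5L, 1L), nrow = 4,
                 dimnames = list(paste0("s", 1:4), c("A", "B")))
    input <- matrix(c(0L, 7L, 5L, 9L,
                      8L, 3L, 5L, 0L), nrow = 4,
                    dimnames = dimnames(ip))
    MeripCountSet(ip, input, geneIds = paste0("g", 1:4))
}

# MethylationMatrix straight from matrices (for distance/cluster tests)
methFixture <- function(values, coverage = NULL, stage = "standardized",
                        scale = "beta") {
    values <- as.matrix(values)
    if (is.null(coverage))
        coverage <- matrix(100, nrow(values), ncol(values))
    if (is.null(rownames(values)))
        rownames(values) <- paste0("s", seq_len(nrow(values)))
    dimnames(coverage) <- dimnames(values)
    new("MethylationMatrix", values = values,
        coverage = as.matrix(coverage), stage = stage, scale = scale,
        geneIds = character())
}

# benchmark dataset collection under the generator defaults
benchmarkSuite <- function(seeds, ...) {
    lapply(seeds, function(s) {
        ds <- makeSampleBenchmark(seed = s, ...)
        list(counts = prepareSampleDataset(ds$counts),
             groups = ds$truth$sampleGroups)
    })
}

# brute-force weighted distance: naive per-pair double loop oracle
naivePairwise <- function(x, v, scheme, metric) {
    n <- nrow(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        w <- pairWeights(scheme, pairCoverage(v[i, ], v[j, ]))
        d[i, j] <- weightedDistance(x[i, ], x[j, ], w, metric)
    }
    d
}

# brute-force hypergeometric upper tail by enumeration over all draws
enumHyper <- function(k, K, n, N) {
    sum(vapply(k:min(K, n), function(x)
        choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}
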