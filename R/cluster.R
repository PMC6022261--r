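## Hierarchical clustering, the exact-partition sample benchmark,
## random-guess analytics, silhouette model selection and the
## (alpha, beta, N) grid search.

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the chosen linkage, cut into k flat
#' clusters. Complete linkage is the default: it is invariant under
#' monotone transforms of the distances, so the uniform-weight 1/sqrt(S)
#' rescaling of the Euclidean metric cannot change the result.
#'
#' @param object a \linkS4class{DistanceMatrix}.
#' @param k number of clusters, 2 <= k <= N (k = 1 and k = N allowed as
#'   degenerate cuts).
#' @param linkage \code{"complete"} (default), \code{"average"},
#'   \code{"single"} or \code{"ward"} (Ward.D2).
#' @return A \linkS4class{ClusteringResult}.
#' @export
hierarchicalCluster <- function(object, k,
                                linkage = c("complete", "average",
                                            "single", "ward")) {
    linkage <- match.arg(linkage)
    m <- distMatrix(object)
    n <- nrow(m)
    if (k < 1 || k > n) stop("'k' must lie in [1, ", n, "]")
    method <- if (linkage == "ward") "ward.D2" else linkage
    tree <- stats::hclust(stats::as.dist(m), method = method)
    labels <- stats::cutree(tree, k = k)
    methods::new("ClusteringResult", tree = tree,
                 labels = stats::setNames(as.integer(labels), names(labels)),
                 k = as.integer(k), linkage = linkage)
}

#' Exact-match comparison of two partitions
#'
#' TRUE iff the two label vectors induce the same partition, i.e. are
#' identical up to cluster relabeling — the stringent criterion under
#' which a clustering of samples counts as correct only when every
#' sample is placed correctly.
#'
#' @param pred,truth label vectors of equal length (any atomic type).
#' @return Logical scalar.
#' @export
exactMatch <- function(pred, truth) {
    if (length(pred) != length(truth)) stop("label vectors differ in length")
    identical(match(pred, unique(pred)), match(truth, unique(truth)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement in [-1, 1]; 1 iff the
#' partitions are identical up to relabeling.
#'
#' @param pred,truth label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjustedRand <- function(pred, truth) {
    if (length(pred) != length(truth)) stop("label vectors differ in length")
    mclust::adjustedRandIndex(pred, truth)
}

#' Number of unordered bipartitions of n labeled items
#'
#' The count of ways to split n labeled items into 2 non-empty,
#' unordered groups: 2^(n-1) - 1. For 6 samples there are 31, so a
#' random guess is exactly right with probability 1/31 (about 3.2%).
#'
#' @param n number of items, >= 2.
#' @return Integer-valued numeric.
#' @export
countBipartitions <- function(n) {
    if (n < 2) stop("'n' must be at least 2")
    2^(n - 1) - 1
}

#' Probability that a uniform random bipartition is exactly correct
#'
#' @inheritParams countBipartitions
#' @return 1 / [countBipartitions()].
#' @export
randomPartitionCorrectProb <- function(n) 1 / countBipartitions(n)

#' Prepare a small sample-clustering dataset
#'
#' Per-sample preprocessing for the sample-label benchmark: size
#' factors from column totals, beta-value methylation levels, quantile
#' normalization across samples, and row standardization (constant
#' rows — typically fully uncovered sites — centered to 0, where they
#' are neutral). No replicate merging: the samples are the entities to
#' cluster.
#'
#' @param counts a \linkS4class{MeripCountSet} of raw samples.
#' @return A standardized \linkS4class{MethylationMatrix} (sites x
#'   samples).
#' @export
prepareSampleDataset <- function(counts) {
    x <- estimateSizeFactors(counts)
    m <- computeMethylation(x)
    m <- quantileNormalize(m)
    standardizeRows(m, constant = "zero")
}

#' Cluster the samples of one dataset
#'
#' @param meth a prepared \linkS4class{MethylationMatrix} (see
#'   [prepareSampleDataset()]) or a \linkS4class{MeripCountSet}, which
#'   is prepared first.
#' @param k number of sample groups.
#' @param scheme,metric,linkage see [pairwiseDistances()] and
#'   [hierarchicalCluster()].
#' @return A \linkS4class{ClusteringResult} over the samples.
#' @export
clusterSamples <- function(meth, k = 2, scheme = WeightingScheme("none"),
                           metric = "euclidean", linkage = "complete") {
    if (methods::is(meth, "MeripCountSet")) meth <- prepareSampleDataset(meth)
    d <- pairwiseDistances(meth, scheme = scheme, metric = metric,
                           axis = "samples")
    hierarchicalCluster(d, k = k, linkage = linkage)
}

#' Exact-match benchmark over a collection of labeled datasets
#'
#' Clusters the samples of every dataset into its true number of groups
#' and returns the fraction of datasets whose predicted partition
#' matches the true sample labels exactly.
#'
#' @param datasets a list; each element is a list with components
#'   \code{counts} (a \linkS4class{MeripCountSet}, or a prepared
#'   \linkS4class{MethylationMatrix}) and \code{groups} (true sample
#'   group labels).
#' @param scheme,metric,linkage passed to [clusterSamples()].
#' @return Mean exact-match fraction in [0, 1].
#' @export
benchmarkSampleClustering <- function(datasets,
                                      scheme = WeightingScheme("none"),
                                      metric = "euclidean",
                                      linkage = "complete") {
    if (length(datasets) == 0) stop("empty dataset collection")
    hits <- vapply(datasets, function(ds) {
        truth <- ds$groups
        cl <- clusterSamples(ds$counts, k = length(unique(truth)),
                             scheme = scheme, metric = metric,
                             linkage = linkage)
        exactMatch(clusterLabels(cl), truth)
    }, logical(1))
    mean(hits)
}

#' Mean silhouette coefficient of a flat clustering
#'
#' For each entity, a is its mean distance to its own cluster
#' (excluding itself) and b the smallest mean distance to any other
#' cluster; its silhouette width is (b - a) / max(a, b), with
#' singleton clusters contributing 0. The mean width measures how well
#' the partition separates; values near 0 indicate no clear cluster
#' structure.
#'
#' @param object a \linkS4class{DistanceMatrix}.
#' @param labels flat cluster labels covering at least 2 clusters.
#' @return Mean silhouette width.
#' @export
silhouetteMean <- function(object, labels) {
    if (length(unique(labels)) < 2)
        stop("silhouette needs at least 2 clusters")
    sil <- cluster::silhouette(as.integer(factor(labels)),
                               dmatrix = distMatrix(object))
    mean(sil[, "sil_width"])
}

#' Grid search over the threshold scheme's parameters
#'
#' For every combination of alpha quantile, beta and dataset size,
#' draws \code{reps} seeded benchmark datasets (shared across the
#' (alpha, beta) grid for a given size and repetition, so parameter
#' effects are not confounded by sampling noise) and records the mean
#' exact-match accuracy of threshold-weighted sample clustering. The
#' default grids are the canonical ones: alpha in [0, 0.05, 0.15, ...,
#' 0.95], beta spanning 1e-4 to 7.5 (values above 1 as negative
#' control), sizes 10 to 100 sites.
#'
#' @param alphaGrid,betaGrid,sizeGrid parameter axes.
#' @param reps datasets per cell (default 100).
#' @param seed root seed; per-(size, repetition) child seeds are
#'   derived deterministically so any cell can be reproduced alone.
#' @param metric,linkage passed to [clusterSamples()].
#' @param ... further arguments to [makeSampleBenchmark()] (e.g.
#'   \code{lowCoverageFraction}, \code{effectSize}).
#' @return A long-format \code{data.frame} with columns \code{alpha},
#'   \code{beta}, \code{n_sites}, \code{accuracy}, \code{reps},
#'   \code{seed}.
#' @export
gridSearch <- function(alphaGrid = c(0, 0.05, 0.15, 0.25, 0.35, 0.45,
                                     0.50, 0.55, 0.65, 0.75, 0.85, 0.95),
                       betaGrid = c(1e-4, 5e-4, 2.5e-3, 1.35e-2, 0.03,
                                    0.045, 0.06, 0.09, 0.135, 0.15, 0.3,
                                    0.75, 1, 1.5, 7.5),
                       sizeGrid = seq(10, 100, by = 10),
                       reps = 100, seed = 1, metric = "euclidean",
                       linkage = "complete", ...) {
    if (!length(alphaGrid) || !length(betaGrid) || !length(sizeGrid))
        stop("parameter grids must be non-empty")
    if (reps < 1) stop("'reps' must be at least 1")
    out <- list()
    for (n in sizeGrid) {
        datasets <- lapply(seq_len(reps), function(r) {
            ds <- makeSampleBenchmark(nSites = n,
                                      seed = childSeed(seed, n, r), ...)
            list(counts = prepareSampleDataset(ds$counts),
                 groups = ds$truth$sampleGroups)
        })
        for (a in alphaGrid) for (b in betaGrid) {
            acc <- benchmarkSampleClustering(
                datasets,
                scheme = WeightingScheme("threshold", alphaQuantile = a,
                                         beta = b),
                metric = metric, linkage = linkage)
            out[[length(out) + 1L]] <-
                data.frame(alpha = a, beta = b, n_sites = n,
                           accuracy = acc, reps = reps, seed = seed)
        }
    }
    do.call(rbind, out)
}

## Deterministic child seed below 2^31, so any grid cell or benchmark
## repetition can be regenerated in isolation.
childSeed <- function(seed, ...) {
    parts <- c(seed, ...)
    h <- 0
    for (p in parts) h <- (h * 7919 + as.numeric(p) * 1e4 + 17) %% 2147483629
    as.integer(floor(h)) + 1L
}
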