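## Seeded generator of MeRIP-seq-like count data with planted modules,
## heterogeneous coverage, and the 6-sample / 2-group benchmark design.
##
## Noise model: reads at a site under a condition are a mixture of
## signal and nonspecific background. Signal totals follow
## Poisson(lambda_site * depth_condition) and split binomially with the
## site's methylation level pi, so the estimated level t / (t + c) is
## centered on pi with variance shrinking as 1/coverage. Background
## totals follow Poisson(backgroundRate) and split with a random,
## pi-independent IP fraction — the nonspecific antibody binding that
## dominates the IP/input ratio wherever signal reads are scarce. A
## well-covered site is barely touched by background; a lowly expressed
## site's estimate is mostly background noise however many of its few
## reads one counts. Per-site lambda are log-normal (a few highly
## expressed sites, many lowly expressed ones), and a configurable
## fraction of sites is forced to near-zero signal to mimic unreliably
## measured lowly expressed genes.

#' Simulate a MeRIP-seq count set with planted site modules
#'
#' @param nSites number of methylation sites.
#' @param nConditions number of experimental conditions S.
#' @param nModules number of planted modules K (used when
#'   \code{moduleProfiles} is NULL).
#' @param moduleSizes integer vector summing to \code{nSites}
#'   (default: near-equal split).
#' @param moduleProfiles K x S matrix of module methylation levels in
#'   (0, 1); by default drawn uniformly in [0.1, 0.9].
#' @param muLog,sigmaLog log-normal parameters of the per-site mean
#'   coverage lambda (defaults log(100) and 1: median 100 reads with
#'   heavy right tail).
#' @param depth per-condition relative sequencing depth (positive,
#'   default all 1).
#' @param lowCoverageFraction fraction of measurements (site-condition
#'   cells) whose signal coverage is forced down to \code{lowLambda}
#'   (default 0). Coverage loss in real data is per measurement — a
#'   gene well expressed in one condition may be silent in another —
#'   so the injection is per cell, not per site.
#' @param lowLambda mean signal coverage of the forced low-coverage
#'   measurements (default 1).
#' @param jitterConcentration concentration of the per-site Beta jitter
#'   around the module profile (larger = tighter; default 100).
#' @param backgroundRate expected nonspecific background reads per
#'   measurement (default 3), split between IP and input with a random
#'   IP fraction independent of the methylation level.
#' @param seed root seed; all randomness is derived from it.
#' @return A list with \code{counts} (a \linkS4class{MeripCountSet},
#'   one sample per condition) and \code{truth} (list with
#'   \code{siteModules}, \code{profiles}, \code{lambda}).
#' @export
simulateCounts <- function(nSites = 1000, nConditions = 9, nModules = 5,
                           moduleSizes = NULL, moduleProfiles = NULL,
                           muLog = log(100), sigmaLog = 1,
                           depth = rep(1, nConditions),
                           lowCoverageFraction = 0, lowLambda = 1,
                           jitterConcentration = 100, backgroundRate = 3,
                           seed = 1) {
    if (nSites < 2 || nConditions < 2) stop("need >= 2 sites and conditions")
    if (sigmaLog < 0) stop("'sigmaLog' must be non-negative")
    if (any(depth <= 0) || length(depth) != nConditions)
        stop("'depth' must be positive, one value per condition")
    if (lowCoverageFraction < 0 || lowCoverageFraction > 1)
        stop("'lowCoverageFraction' must lie in [0, 1]")
    if (is.null(moduleSizes)) {
        moduleSizes <- rep(nSites %/% nModules, nModules)
        moduleSizes[seq_len(nSites %% nModules)] <-
            moduleSizes[seq_len(nSites %% nModules)] + 1L
    }
    if (sum(moduleSizes) != nSites)
        stop("'moduleSizes' must sum to 'nSites'")
    K <- length(moduleSizes)

    set.seed(childSeed(seed, 101))
    if (is.null(moduleProfiles))
        moduleProfiles <- matrix(runif(K * nConditions, 0.1, 0.9),
                                 K, nConditions)
    if (any(moduleProfiles <= 0) || any(moduleProfiles >= 1))
        stop("'moduleProfiles' must lie strictly inside (0, 1)")
    siteModules <- rep(seq_len(K), moduleSizes)

    ## per-site expression scale, with low coverage forced on a random
    ## subset of measurements (site-condition cells)
    set.seed(childSeed(seed, 102))
    lambda <- exp(stats::rnorm(nSites, muLog, sigmaLog))
    lamMat <- matrix(lambda, nSites, nConditions)
    nLow <- round(lowCoverageFraction * length(lamMat))
    lowIdx <- if (nLow > 0) sample.int(length(lamMat), nLow) else integer()
    lamMat[lowIdx] <- lowLambda

    ## per-site jitter around the module profile
    set.seed(childSeed(seed, 103))
    piMat <- moduleProfiles[siteModules, , drop = FALSE]
    piMat <- matrix(stats::rbeta(length(piMat),
                                 piMat * jitterConcentration,
                                 (1 - piMat) * jitterConcentration),
                    nSites, nConditions)
    piMat <- pmin(pmax(piMat, 1e-6), 1 - 1e-6)

    set.seed(childSeed(seed, 104))
    cnt <- .mixtureCounts(lamMat * rep(depth, each = nSites), piMat,
                          backgroundRate, nSites, nConditions)
    t <- cnt$t; c <- cnt$c
    ids <- sprintf("site_%04d", seq_len(nSites))
    dimnames(t) <- dimnames(c) <-
        list(ids, sprintf("cond_%02d", seq_len(nConditions)))
    counts <- MeripCountSet(t, c, geneIds = sprintf("gene_%04d",
                                                    seq_len(nSites)))
    list(counts = counts,
         truth = list(siteModules = stats::setNames(siteModules, ids),
                      profiles = moduleProfiles, lambda = lambda,
                      lowCoverage = lowIdx))
}

#' Simulate one small sample-label benchmark dataset
#'
#' Emulates the benchmark design of two replicate groups (e.g. treated
#' vs control, 3 replicates each) profiled over a handful of
#' methylation sites: a subset of sites shifts its methylation level
#' between the groups by \code{effectSize}, the rest are static, and a
#' fraction of sites is forced to near-zero coverage so their estimated
#' levels are noise. Clustering the samples should recover the two
#' groups.
#'
#' @param nSites number of sites (default 30).
#' @param nReplicatesPerGroup samples per group (default 3, giving the
#'   6-sample design).
#' @param lowCoverageFraction fraction of sites with near-zero coverage
#'   (default 0.45).
#' @param effectSize between-group shift of the methylation level of
#'   dynamic sites, in (0, 1) (default 0.25).
#' @param dynamicFraction fraction of sites carrying the group effect
#'   (default 0.5).
#' @param muLog,sigmaLog log-normal coverage scale of expressed sites
#'   (defaults log(50) and 1).
#' @param lowLambda mean coverage of low-coverage sites (default 1).
#' @param jitterConcentration per-site replicate-level Beta jitter
#'   (default 60).
#' @param backgroundRate expected nonspecific background reads per
#'   measurement (default 3).
#' @param seed root seed.
#' @return A list with \code{counts} (a \linkS4class{MeripCountSet}
#'   whose samples are the entities to cluster) and \code{truth}
#'   (list with \code{sampleGroups}, \code{dynamicSites}).
#' @export
makeSampleBenchmark <- function(nSites = 30, nReplicatesPerGroup = 3,
                                lowCoverageFraction = 0.45,
                                effectSize = 0.25, dynamicFraction = 0.5,
                                muLog = log(100), sigmaLog = 1.25,
                                lowLambda = 1, jitterConcentration = 60,
                                backgroundRate = 3, seed = 1) {
    if (nSites < 2) stop("'nSites' must be at least 2")
    if (effectSize <= 0 || effectSize >= 1)
        stop("'effectSize' must lie strictly inside (0, 1)")
    nSamples <- 2L * nReplicatesPerGroup
    groups <- rep(c("g1", "g2"), each = nReplicatesPerGroup)

    set.seed(childSeed(seed, 201))
    base <- runif(nSites, 0.15, 0.85)
    nDyn <- max(1L, round(dynamicFraction * nSites))
    dynIdx <- sample.int(nSites, nDyn)
    sgn <- sample(c(-1, 1), nDyn, replace = TRUE)
    pi1 <- pi2 <- base
    pi2[dynIdx] <- pmin(pmax(base[dynIdx] + sgn * effectSize, 0.02), 0.98)

    set.seed(childSeed(seed, 202))
    lambda <- exp(stats::rnorm(nSites, muLog, sigmaLog))
    nLow <- round(lowCoverageFraction * nSites)
    lowIdx <- if (nLow > 0) sample.int(nSites, nLow) else integer()
    lambda[lowIdx] <- lowLambda

    set.seed(childSeed(seed, 203))
    piMat <- cbind(matrix(pi1, nSites, nReplicatesPerGroup),
                   matrix(pi2, nSites, nReplicatesPerGroup))
    piMat <- matrix(stats::rbeta(length(piMat),
                                 piMat * jitterConcentration,
                                 (1 - piMat) * jitterConcentration),
                    nSites, nSamples)
    piMat <- pmin(pmax(piMat, 1e-6), 1 - 1e-6)

    set.seed(childSeed(seed, 204))
    cnt <- .mixtureCounts(lambda, piMat, backgroundRate, nSites, nSamples)
    t <- cnt$t; c <- cnt$c
    ids <- sprintf("site_%04d", seq_len(nSites))
    smp <- sprintf("%s_r%d", groups, rep(seq_len(nReplicatesPerGroup), 2))
    dimnames(t) <- dimnames(c) <- list(ids, smp)
    counts <- MeripCountSet(t, c, condition = smp,
                            geneIds = sprintf("gene_%04d", seq_len(nSites)))
    list(counts = counts,
         truth = list(sampleGroups = stats::setNames(groups, smp),
                      dynamicSites = ids[sort(dynIdx)],
                      lowCoverage = ids[sort(lowIdx)]))
}

#' Build a synthetic gene-annotation table
#'
#' Random term-to-gene sets over a gene universe, optionally with one
#' planted term covering a designated gene set (to give enrichment
#' analysis a known positive).
#'
#' @param genes character vector of gene ids (the universe).
#' @param nTerms number of random terms (default 50).
#' @param termSizeRange integer range of term sizes (default c(5, 50)).
#' @param plantedGenes optional character vector of genes forming a
#'   planted term \code{"TERM_planted"}.
#' @param seed root seed.
#' @return A \code{data.frame} with columns \code{term_id} and
#'   \code{gene_id} (long format, one row per term-gene link).
#' @export
makeAnnotation <- function(genes, nTerms = 50, termSizeRange = c(5, 50),
                           plantedGenes = NULL, seed = 1) {
    if (max(termSizeRange) > length(genes))
        stop("term sizes exceed the gene universe")
    set.seed(childSeed(seed, 301))
    rows <- lapply(seq_len(nTerms), function(i) {
        sz <- sample(seq(termSizeRange[1], termSizeRange[2]), 1)
        data.frame(term_id = sprintf("TERM_%03d", i),
                   gene_id = sample(genes, sz))
    })
    if (!is.null(plantedGenes)) {
        if (!all(plantedGenes %in% genes))
            stop("planted genes must belong to the universe")
        rows <- c(rows, list(data.frame(term_id = "TERM_planted",
                                        gene_id = plantedGenes)))
    }
    do.call(rbind, rows)
}

## signal + background mixture: signal reads split by pi, background
## reads by a random pi-independent IP fraction (Beta(2, 2))
.mixtureCounts <- function(lambda, piMat, backgroundRate, nr, nc) {
    n <- nr * nc
    sigTot <- stats::rpois(n, lambda)
    sigIp <- stats::rbinom(n, sigTot, piMat)
    bgTot <- stats::rpois(n, backgroundRate)
    bgFrac <- stats::rbeta(n, 2, 2)
    bgIp <- stats::rbinom(n, bgTot, bgFrac)
    list(t = matrix(sigIp + bgIp, nr, nc),
         c = matrix((sigTot - sigIp) + (bgTot - bgIp), nr, nc))
}
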