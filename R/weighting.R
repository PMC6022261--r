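## Reliability weights for a pair of methylation profiles, derived from
## the read coverage supporting each shared measurement.

#' Combined coverage of a profile pair, per dimension
#'
#' For sites i and j the pair coverage in condition s is
#' t_i + c_i + t_j + c_j: the total number of reads behind both
#' measurements being compared.
#'
#' @param vi,vj per-dimension coverage vectors of the two profiles.
#' @return Element-wise sum, same length.
#' @export
pairCoverage <- function(vi, vj) {
    if (length(vi) != length(vj)) stop("coverage vectors differ in length")
    vi + vj
}

#' Logarithm-based reliability weights
#'
#' Raw weight log(v + 1) per dimension, normalized to sum to 1.
#' Reliability grows quickly at low coverage and saturates: 2 vs 200
#' reads is a large difference, 1002 vs 1202 a minor one. If every
#' dimension has zero coverage all raw weights vanish and the uniform
#' weight 1/S is returned so a distance is always defined.
#'
#' @param v non-negative pair-coverage vector (see [pairCoverage()]).
#' @return Normalized weights (non-negative, summing to 1).
#' @examples
#' logWeights(c(3, 7)) # exactly (0.4, 0.6)
#' @export
logWeights <- function(v) {
    if (any(v < 0)) stop("coverage must be non-negative")
    w <- log(v + 1)
    s <- sum(w)
    if (s == 0) return(rep(1 / length(v), length(v)))
    w / s
}

#' Threshold-based reliability weights
#'
#' Raw weight 1 for dimensions whose pair coverage reaches the count
#' threshold, beta below it, normalized to sum to 1. beta = 1 (or a
#' threshold of 0) penalizes nothing and reproduces uniform weights;
#' beta > 1 up-weights the unreliable dimensions (negative control).
#' A degenerate all-zero raw vector (beta = 0 with every dimension
#' below threshold) falls back to uniform weights.
#'
#' @param v non-negative pair-coverage vector.
#' @param threshold count threshold (see [resolveAlpha()]).
#' @param beta reduced weight for sub-threshold dimensions (>= 0).
#' @return Normalized weights (non-negative, summing to 1).
#' @examples
#' thresholdWeights(c(10, 2), threshold = 5, beta = 0.1) # (10/11, 1/11)
#' @export
thresholdWeights <- function(v, threshold, beta) {
    if (beta < 0) stop("'beta' must be non-negative")
    w <- ifelse(v >= threshold, 1, beta)
    s <- sum(w)
    if (s == 0) return(rep(1 / length(v), length(v)))
    w / s
}

#' Resolve the alpha quantile into a count threshold
#'
#' The threshold parameter of the threshold scheme is specified as a
#' quantile (alpha) of the empirical distribution of pairwise coverage
#' sums v_{s,i,j} over all profile pairs and dimensions, so that e.g.
#' alpha = 0.45 penalizes the least-covered 45% of pair measurements
#' regardless of sequencing depth. With at most \code{exactPairLimit}
#' entities all pairs are enumerated; beyond that,
#' \code{pairSampleSize} seeded random pairs approximate the
#' distribution. Quantiles use linear interpolation between order
#' statistics (type 7). alpha = 0 resolves to threshold 0, penalizing
#' nothing.
#'
#' @param scheme a \linkS4class{WeightingScheme} of kind
#'   \code{"threshold"} (other kinds are returned unchanged).
#' @param coverage entity-by-dimension coverage matrix (entities in
#'   rows: sites, or samples after transposition).
#' @param exactPairLimit maximum entity count for exhaustive pair
#'   enumeration (default 2000).
#' @return The scheme with \code{resolvedThreshold} cached.
#' @export
resolveAlpha <- function(scheme, coverage, exactPairLimit = 2000L) {
    if (scheme@kind != "threshold") return(scheme)
    coverage <- as.matrix(coverage)
    storage.mode(coverage) <- "double"
    n <- nrow(coverage)
    if (n < 2 || length(coverage) == 0) stop("empty coverage distribution")
    if (scheme@alphaQuantile == 0) {
        scheme@resolvedThreshold <- 0
        return(scheme)
    }
    if (n <= exactPairLimit) {
        scheme@resolvedThreshold <- .quantile7(.pairSumsCpp(coverage),
                                               scheme@alphaQuantile)
        return(scheme)
    } else {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(scheme@seed)
        m <- scheme@pairSampleSize
        i <- sample.int(n, m, replace = TRUE)
        j <- sample.int(n - 1L, m, replace = TRUE)
        j <- ifelse(j >= i, j + 1L, j)
        idx <- cbind(i, j)
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    sums <- coverage[idx[, 1], , drop = FALSE] +
            coverage[idx[, 2], , drop = FALSE]
    scheme@resolvedThreshold <- .quantile7(as.vector(sums),
                                           scheme@alphaQuantile)
    scheme
}

## type-7 quantile via partial sort: identical to stats::quantile(type = 7)
## but O(n) instead of a full sort, which matters over millions of pair sums
.quantile7 <- function(x, p) {
    n <- length(x)
    h <- (n - 1) * p
    j <- floor(h) + 1L
    k <- min(j + 1L, n)
    xs <- sort(x, partial = unique(c(j, k)))
    lo <- xs[j]; hi <- xs[k]
    unname(lo + (h - (j - 1L)) * (hi - lo))
}

#' Weights for one profile pair under a scheme
#'
#' Dispatches on the scheme kind; the threshold scheme must already be
#' resolved (see [resolveAlpha()]).
#'
#' @param scheme a \linkS4class{WeightingScheme}.
#' @param v pair-coverage vector.
#' @return Normalized weights.
#' @export
pairWeights <- function(scheme, v) {
    switch(scheme@kind,
        none = rep(1 / length(v), length(v)),
        logarithm = logWeights(v),
        threshold = {
            if (is.na(scheme@resolvedThreshold))
                stop("threshold scheme not resolved; call resolveAlpha()")
            thresholdWeights(v, scheme@resolvedThreshold, scheme@beta)
        })
}
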