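## Weighted pairwise dissimilarities between methylation profiles.
##
## For profiles x_i, x_j with normalized per-dimension weights w:
##   euclidean          sqrt(sum_s w_s (x_i - x_j)_s^2)
##   squared_euclidean  sum_s w_s (x_i - x_j)_s^2
##   cityblock          sum_s w_s |x_i - x_j|_s
## Weights are convex, so unweighted (kind = "none") euclidean equals the
## classic Euclidean distance divided by sqrt(S) — a monotone rescaling
## that leaves dendrogram topology untouched.

.metrics <- c("euclidean", "squared_euclidean", "cityblock")

#' Weighted dissimilarity between two profiles
#'
#' @param xi,xj numeric profiles of equal length.
#' @param w normalized weights (non-negative, summing to 1 within
#'   1e-8).
#' @param metric one of \code{"euclidean"}, \code{"squared_euclidean"},
#'   \code{"cityblock"}.
#' @return A non-negative scalar.
#' @export
weightedDistance <- function(xi, xj, w,
                             metric = c("euclidean", "squared_euclidean",
                                        "cityblock")) {
    metric <- match.arg(metric)
    if (length(xi) != length(xj) || length(xi) != length(w))
        stop("profiles and weights must have equal length")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        stop("weights must be non-negative and sum to 1")
    d <- xi - xj
    switch(metric,
        euclidean = sqrt(sum(w * d^2)),
        squared_euclidean = sum(w * d^2),
        cityblock = sum(w * abs(d)))
}

#' All pairwise weighted distances between sites or samples
#'
#' Computes the full symmetric distance matrix between methylation
#' profiles. With \code{axis = "sites"} the entities are sites and the
#' weighted dimensions are the conditions; with \code{axis = "samples"}
#' the roles transpose — entities are samples, dimensions are sites,
#' and the pair coverage of a sample pair in dimension n is
#' v[n, i] + v[n, j]. An unresolved threshold scheme is resolved
#' against this matrix's own coverage (the resolved count threshold is
#' recorded in the result's scheme).
#'
#' @param object a \linkS4class{MethylationMatrix} carrying coverage.
#' @param scheme a \linkS4class{WeightingScheme} (default: no
#'   weighting).
#' @param metric see [weightedDistance()].
#' @param axis \code{"sites"} (default) or \code{"samples"}.
#' @param maxEntities guard against accidental huge dense matrices
#'   (default 20000).
#' @return A \linkS4class{DistanceMatrix}.
#' @export
pairwiseDistances <- function(object, scheme = WeightingScheme("none"),
                              metric = c("euclidean", "squared_euclidean",
                                         "cityblock"),
                              axis = c("sites", "samples"),
                              maxEntities = 20000L) {
    metric <- match.arg(metric)
    axis <- match.arg(axis)
    x <- methLevels(object)
    v <- methCoverage(object)
    if (axis == "samples") { x <- t(x); v <- t(v) }
    n <- nrow(x)
    if (n < 2) stop("need at least 2 entities on axis '", axis, "'")
    if (n > maxEntities)
        stop(n, " entities exceed 'maxEntities' (", maxEntities, ")")
    if (scheme@kind == "threshold" && is.na(scheme@resolvedThreshold))
        scheme <- resolveAlpha(scheme, v)
    d <- .pairwiseCore(x, v, scheme, metric)
    dimnames(d) <- list(rownames(x), rownames(x))
    methods::new("DistanceMatrix", mat = d, metric = metric,
                 scheme = scheme, axis = axis)
}

## The per-pair accumulation lives in compiled code (src/pairwise.cpp):
## for every pair, raw weights over the dimensions are normalized and
## applied to the coordinate deviations in one pass.
.pairwiseCore <- function(x, v, scheme, metric) {
    storage.mode(x) <- storage.mode(v) <- "double"
    kind <- match(scheme@kind, c("none", "logarithm", "threshold")) - 1L
    met <- match(metric, .metrics) - 1L
    thr <- if (is.na(scheme@resolvedThreshold)) 0 else scheme@resolvedThreshold
    .pairwiseCoreCpp(x, v, kind, thr, scheme@beta, met)
}

#' Write a distance matrix as labeled TSV
#'
#' @param object a \linkS4class{DistanceMatrix}.
#' @param path output file.
#' @export
writeDistanceTSV <- function(object, path) {
    m <- distMatrix(object)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
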