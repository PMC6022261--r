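#' @import methods
#' @useDynLib meripModules, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats quantile sd var rbinom rpois rbeta runif phyper
#'   fisher.test hclust cutree as.dist setNames wilcox.test binom.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

setOldClass("hclust")

#' MeripCountSet: per-site IP/input read counts across samples
#'
#' A \linkS4class{SummarizedExperiment} subclass holding two assays,
#' \code{"ip"} (immunoprecipitated library counts) and \code{"input"}
#' (background library counts), for N methylation sites by S samples.
#' \code{colData} carries the experimental \code{condition} of every
#' sample column plus library size factors (\code{sizeFactorIP},
#' \code{sizeFactorInput}, \code{NA} until estimated); \code{rowData}
#' carries the \code{gene_id} of every site.
#'
#' @seealso [MeripCountSet()], [mergeReplicates()], [computeMethylation()]
#' @export
setClass("MeripCountSet", contains = "SummarizedExperiment")

setValidity("MeripCountSet", function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("ip", "input") %in% an))
        msg <- c(msg, "assays must include 'ip' and 'input'")
    else {
        for (a in c("ip", "input")) {
            m <- SummarizedExperiment::assay(object, a)
            if (any(is.na(m)) || any(m < 0))
                msg <- c(msg, sprintf("assay '%s' must be non-negative", a))
            else if (any(m != round(m)))
                msg <- c(msg, sprintf("assay '%s' must hold integer counts", a))
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "site ids (rownames) must be present and unique")
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    if (is.null(msg)) TRUE else msg
})

#' MethylationMatrix: methylation levels with coverage carried alongside
#'
#' Sites-by-conditions matrix of methylation levels, together with the
#' read coverage v = t + c of every measurement, which downstream
#' distance computations use as a reliability signal. The \code{stage}
#' label records where in the preprocessing pipeline the values sit
#' (\code{raw}, \code{quantile_normalized}, \code{selected},
#' \code{standardized}); \code{scale} records whether values are beta
#' fractions in [0, 1] or log-ratio M-values.
#'
#' @seealso [computeMethylation()], [quantileNormalize()],
#'   [selectDynamicSites()], [standardizeRows()]
#' @export
setClass("MethylationMatrix",
    representation(values = "matrix", coverage = "matrix",
                   stage = "character", scale = "character",
                   geneIds = "character"))

setValidity("MethylationMatrix", function(object) {
    msg <- NULL
    v <- object@values; cv <- object@coverage
    if (!identical(dim(v), dim(cv)))
        msg <- c(msg, "values and coverage must have identical dimensions")
    if (!object@stage %in% c("raw", "quantile_normalized", "selected",
                             "standardized"))
        msg <- c(msg, "unknown stage label")
    if (!object@scale %in% c("beta", "mvalue"))
        msg <- c(msg, "scale must be 'beta' or 'mvalue'")
    if (object@scale == "beta" && object@stage != "standardized" &&
        length(v) && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "beta-scale values must lie in [0, 1]")
    if (any(cv < 0)) msg <- c(msg, "coverage must be non-negative")
    if (length(object@geneIds) && length(object@geneIds) != nrow(v))
        msg <- c(msg, "geneIds must have one entry per site")
    if (is.null(msg)) TRUE else msg
})

#' WeightingScheme: how read coverage maps to per-measurement weights
#'
#' Describes the reliability weighting applied to each dimension of a
#' profile pair before computing their distance. \code{kind = "none"}
#' gives uniform weights; \code{"logarithm"} weights a dimension by
#' log(combined coverage + 1); \code{"threshold"} gives weight 1 to
#' dimensions whose combined pair coverage reaches a count threshold and
#' a reduced weight \code{beta} below it. The threshold is parameterized
#' as the \code{alphaQuantile} of the empirical distribution of pairwise
#' coverage sums and cached in \code{resolvedThreshold} once resolved
#' against a dataset.
#'
#' \code{beta} is not clamped to [0, 1]: values above 1 up-weight the
#' unreliable measurements and serve as a negative control.
#'
#' @seealso [WeightingScheme()], [resolveAlpha()], [thresholdWeights()],
#'   [logWeights()]
#' @export
setClass("WeightingScheme",
    representation(kind = "character", alphaQuantile = "numeric",
                   beta = "numeric", resolvedThreshold = "numeric",
                   pairSampleSize = "integer", seed = "integer"))

setValidity("WeightingScheme", function(object) {
    msg <- NULL
    if (!object@kind %in% c("none", "logarithm", "threshold"))
        msg <- c(msg, "kind must be one of none, logarithm, threshold")
    if (object@alphaQuantile < 0 || object@alphaQuantile >= 1)
        msg <- c(msg, "alphaQuantile must lie in [0, 1)")
    if (object@beta < 0) msg <- c(msg, "beta must be non-negative")
    if (object@pairSampleSize < 1L)
        msg <- c(msg, "pairSampleSize must be positive")
    if (is.null(msg)) TRUE else msg
})

#' DistanceMatrix: pairwise dissimilarities under a weighting scheme
#'
#' Symmetric matrix of pairwise dissimilarities between methylation
#' profiles (of sites or of samples), remembering the metric and the
#' weighting scheme that produced it.
#'
#' @seealso [pairwiseDistances()], [hierarchicalCluster()]
#' @export
setClass("DistanceMatrix",
    representation(mat = "matrix", metric = "character",
                   scheme = "WeightingScheme", axis = "character"))

setValidity("DistanceMatrix", function(object) {
    msg <- NULL
    m <- object@mat
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    else {
        if (!all(is.finite(m))) msg <- c(msg, "entries must be finite")
        else {
            if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
            if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
            if (min(m) < 0) msg <- c(msg, "entries must be non-negative")
        }
    }
    if (!object@metric %in% c("euclidean", "squared_euclidean", "cityblock"))
        msg <- c(msg, "unknown metric")
    if (!object@axis %in% c("sites", "samples"))
        msg <- c(msg, "axis must be 'sites' or 'samples'")
    if (is.null(msg)) TRUE else msg
})

#' ClusteringResult: dendrogram plus a flat k-cut
#'
#' Wraps the agglomerative merge tree and the flat cluster labels
#' obtained by cutting it into \code{k} groups.
#'
#' @seealso [hierarchicalCluster()], [clusterLabels()]
#' @export
setClass("ClusteringResult",
    representation(tree = "hclust", labels = "integer", k = "integer",
                   linkage = "character"))

setValidity("ClusteringResult", function(object) {
    msg <- NULL
    if (length(unique(object@labels)) != object@k)
        msg <- c(msg, "k-cut must produce exactly k non-empty clusters")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MeripCountSet", function(object) {
    cat(sprintf("MeripCountSet: %d sites x %d samples\n",
                nrow(object), ncol(object)))
    cond <- SummarizedExperiment::colData(object)$condition
    cat("conditions:", paste(unique(cond), collapse = ", "), "\n")
    callNextMethod()
})

setMethod("show", "MethylationMatrix", function(object) {
    cat(sprintf("MethylationMatrix: %d sites x %d conditions [%s, %s scale]\n",
                nrow(object@values), ncol(object@values),
                object@stage, object@scale))
    cat(sprintf("median coverage: %g\n", stats::median(object@coverage)))
})

setMethod("show", "WeightingScheme", function(object) {
    cat("WeightingScheme:", object@kind, "\n")
    if (object@kind == "threshold") {
        cat(sprintf("  alpha quantile: %g  beta: %g\n",
                    object@alphaQuantile, object@beta))
        cat(sprintf("  resolved count threshold: %s\n",
                    if (is.na(object@resolvedThreshold)) "<unresolved>"
                    else format(object@resolvedThreshold)))
    }
})

setMethod("show", "DistanceMatrix", function(object) {
    cat(sprintf("DistanceMatrix: %d x %d %s, metric = %s, weighting = %s\n",
                nrow(object@mat), ncol(object@mat), object@axis,
                object@metric, object@scheme@kind))
})

setMethod("show", "ClusteringResult", function(object) {
    cat(sprintf("ClusteringResult: %d entities, %s linkage, k = %d\n",
                length(object@labels), object@linkage, object@k))
    print(table(object@labels))
})
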