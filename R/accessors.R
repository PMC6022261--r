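#' Construct a MeripCountSet from IP and input count matrices
#'
#' @param ip,input integer matrices (sites x samples) of IP and input
#'   read counts, with identical dimensions. Row names are site ids;
#'   column names are sample ids.
#' @param condition character vector mapping each sample column to an
#'   experimental condition (defaults to one condition per column, i.e.
#'   no replication).
#' @param geneIds per-site gene labels used by enrichment analysis
#'   (optional).
#' @param sizeFactorIP,sizeFactorInput per-sample library size factors;
#'   left \code{NA} until [estimateSizeFactors()] is called.
#' @return A \linkS4class{MeripCountSet}.
#' @examples
#' ip <- matrix(rpois(8, 20), 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
#' inp <- matrix(rpois(8, 20), 4, 2, dimnames = dimnames(ip))
#' MeripCountSet(ip, inp)
#' @export
MeripCountSet <- function(ip, input, condition = colnames(ip),
                          geneIds = NULL,
                          sizeFactorIP = rep(NA_real_, ncol(ip)),
                          sizeFactorInput = rep(NA_real_, ncol(ip))) {
    ip <- as.matrix(ip); input <- as.matrix(input)
    if (!identical(dim(ip), dim(input)))
        stop("'ip' and 'input' must have identical dimensions")
    if (is.null(rownames(ip)))
        rownames(ip) <- rownames(input) <- paste0("site_", seq_len(nrow(ip)))
    if (is.null(colnames(ip)))
        colnames(ip) <- colnames(input) <- paste0("sample_", seq_len(ncol(ip)))
    if (is.null(condition)) condition <- colnames(ip)
    if (length(condition) != ncol(ip))
        stop("'condition' must map every sample column")
    rd <- S4Vectors::DataFrame(
        gene_id = if (is.null(geneIds)) rownames(ip) else as.character(geneIds),
        row.names = rownames(ip))
    cd <- S4Vectors::DataFrame(condition = as.character(condition),
                               sizeFactorIP = as.numeric(sizeFactorIP),
                               sizeFactorInput = as.numeric(sizeFactorInput),
                               row.names = colnames(ip))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ip = ip, input = input), rowData = rd, colData = cd)
    methods::new("MeripCountSet", se)
}

#' @rdname counts-accessors
#' @export
ipCounts <- function(object) SummarizedExperiment::assay(object, "ip")

#' Accessors for MeripCountSet components
#'
#' \code{ipCounts}/\code{inputCounts} return the count matrices;
#' \code{siteCoverage} their element-wise sum t + c; \code{conditions}
#' the per-sample condition labels; \code{geneIds} the per-site gene
#' labels; \code{sizeFactors} a two-column matrix of IP and input size
#' factors.
#'
#' @param object a \linkS4class{MeripCountSet}.
#' @name counts-accessors
#' @export
inputCounts <- function(object) SummarizedExperiment::assay(object, "input")

#' @rdname counts-accessors
#' @export
siteCoverage <- function(object) ipCounts(object) + inputCounts(object)

#' @rdname counts-accessors
#' @export
conditions <- function(object) {
    stats::setNames(SummarizedExperiment::colData(object)$condition,
                    colnames(object))
}

#' @rdname counts-accessors
#' @export
geneIds <- function(object) {
    if (methods::is(object, "MethylationMatrix")) return(object@geneIds)
    stats::setNames(SummarizedExperiment::rowData(object)$gene_id,
                    rownames(object))
}

#' @importFrom BiocGenerics sizeFactors
#' @rdname counts-accessors
#' @export
setMethod("sizeFactors", "MeripCountSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cbind(ip = stats::setNames(cd$sizeFactorIP, rownames(cd)),
          input = cd$sizeFactorInput)
})

#' Accessors for MethylationMatrix components
#'
#' @param object a \linkS4class{MethylationMatrix}.
#' @name meth-accessors
#' @export
methLevels <- function(object) object@values

#' @rdname meth-accessors
#' @export
methCoverage <- function(object) object@coverage

#' @rdname meth-accessors
#' @export
methStage <- function(object) object@stage

#' Construct a weighting scheme
#'
#' @param kind one of \code{"none"}, \code{"logarithm"},
#'   \code{"threshold"}.
#' @param alphaQuantile for the threshold scheme: the quantile (in
#'   [0, 1)) of the empirical pairwise-coverage-sum distribution at
#'   which the count threshold is set. 0 means no measurement is
#'   penalized. Default 0.45.
#' @param beta for the threshold scheme: the reduced weight assigned to
#'   measurements below the threshold. Values above 1 up-weight
#'   unreliable measurements (negative control). Default 0.09.
#' @param pairSampleSize number of random site pairs used to resolve the
#'   threshold when exhaustive pair enumeration is too large.
#' @param seed seed for pair sampling during threshold resolution.
#' @return A \linkS4class{WeightingScheme}.
#' @examples
#' WeightingScheme("threshold", alphaQuantile = 0.45, beta = 0.09)
#' @export
WeightingScheme <- function(kind = c("none", "logarithm", "threshold"),
                            alphaQuantile = 0.45, beta = 0.09,
                            pairSampleSize = 100000L, seed = 1L) {
    kind <- match.arg(kind)
    methods::new("WeightingScheme", kind = kind,
                 alphaQuantile = as.numeric(alphaQuantile),
                 beta = as.numeric(beta),
                 resolvedThreshold = NA_real_,
                 pairSampleSize = as.integer(pairSampleSize),
                 seed = as.integer(seed))
}

#' Accessors for DistanceMatrix and ClusteringResult
#'
#' @param object a \linkS4class{DistanceMatrix} or
#'   \linkS4class{ClusteringResult}.
#' @name cluster-accessors
#' @export
distMatrix <- function(object) object@mat

#' @rdname cluster-accessors
#' @export
distScheme <- function(object) object@scheme

#' @rdname cluster-accessors
#' @export
clusterLabels <- function(object) object@labels

#' @rdname cluster-accessors
#' @export
clusterTree <- function(object) object@tree

#' @rdname cluster-accessors
#' @export
resolvedThreshold <- function(object) {
    if (methods::is(object, "DistanceMatrix")) object <- object@scheme
    object@resolvedThreshold
}
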