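## Quantification: raw IP/input counts -> normalized, standardized
## methylation matrix, with per-measurement coverage carried alongside.

#' Merge biological replicates by condition
#'
#' Element-wise sums the IP and input counts of all replicate samples
#' belonging to the same condition, yielding one column per condition.
#' Size factors are reset (they must be estimated on merged counts).
#'
#' @param object a \linkS4class{MeripCountSet} whose \code{colData}
#'   \code{condition} column maps replicates to conditions.
#' @return A \linkS4class{MeripCountSet} with one sample per condition,
#'   in order of first appearance.
#' @export
mergeReplicates <- function(object) {
    cond <- conditions(object)
    if (any(is.na(cond) | cond == ""))
        stop("every replicate column must map to a condition")
    lev <- unique(cond)
    sumBy <- function(m) {
        out <- vapply(lev, function(g) {
            rowSums(m[, cond == g, drop = FALSE])
        }, numeric(nrow(m)))
        out <- matrix(out, nrow = nrow(m),
                      dimnames = list(rownames(m), lev))
        out
    }
    MeripCountSet(sumBy(ipCounts(object)), sumBy(inputCounts(object)),
                  condition = lev, geneIds = geneIds(object))
}

#' Estimate per-sample library size factors from total read counts
#'
#' The size factor of a library is its column total divided by the mean
#' of all column totals of the same type (IP or input), so factors are
#' dimensionless with mean 1 and the methylation-level formula stays
#' scale-neutral. IP and input libraries are normalized separately.
#'
#' @param object a \linkS4class{MeripCountSet} (normally after
#'   [mergeReplicates()]).
#' @param ... unused, kept for generic compatibility.
#' @return The object with \code{sizeFactorIP} and
#'   \code{sizeFactorInput} filled in its \code{colData}.
#' @importFrom BiocGenerics estimateSizeFactors
#' @export
setMethod("estimateSizeFactors", "MeripCountSet", function(object, ...) {
    f <- function(m) {
        tot <- colSums(m)
        if (any(tot == 0))
            stop("all-zero count column: ",
                 paste(colnames(m)[tot == 0], collapse = ", "))
        tot / mean(tot)
    }
    cd <- SummarizedExperiment::colData(object)
    cd$sizeFactorIP <- f(ipCounts(object))
    cd$sizeFactorInput <- f(inputCounts(object))
    SummarizedExperiment::colData(object) <- cd
    object
})

#' Depth-corrected methylation level (beta value)
#'
#' m = (t / d_t) / (t / d_t + c / d_c), the IP fraction after library
#' size correction, in [0, 1]. A measurement with t = c = 0 carries no
#' signal; the uninformative midpoint 0.5 is returned so that the
#' weighting layer, which sees its zero coverage, can suppress it
#' rather than the quantifier dropping the site.
#'
#' @param t,c IP and input read counts (non-negative, vectorized).
#' @param dT,dC positive size factors for the IP and input library.
#' @return Methylation levels in [0, 1].
#' @examples
#' methylationLevel(100, 0) # 1: strong evidence of full methylation
#' methylationLevel(1, 0)   # also 1, but from barely any signal
#' @export
methylationLevel <- function(t, c, dT = 1, dC = 1) {
    if (any(t < 0) || any(c < 0)) stop("counts must be non-negative")
    if (any(dT <= 0) || any(dC <= 0)) stop("size factors must be positive")
    num <- t * dC
    den <- t * dC + c * dT
    out <- ifelse(den == 0, 0.5, num / den)
    out
}

#' Log-ratio methylation status (M-value)
#'
#' M = log2((t / d_t + eps) / (c / d_c + eps)): an unbounded,
#' sign-symmetric alternative to the beta value, with a small additive
#' offset guarding zero counts.
#'
#' @inheritParams methylationLevel
#' @param eps positive additive offset (default 0.5).
#' @return M-values (unbounded reals).
#' @export
mValue <- function(t, c, dT = 1, dC = 1, eps = 0.5) {
    if (any(t < 0) || any(c < 0)) stop("counts must be non-negative")
    if (eps <= 0) stop("'eps' must be positive")
    log2((t / dT + eps) / (c / dC + eps))
}

#' Compute the methylation matrix from a count set
#'
#' Applies [methylationLevel()] (or [mValue()]) element-wise using the
#' stored size factors, and attaches the raw coverage v = t + c of every
#' measurement for later reliability weighting.
#'
#' @param object a \linkS4class{MeripCountSet} with size factors
#'   estimated (unit factors assumed, with a warning, if not).
#' @param scale \code{"beta"} (default) or \code{"mvalue"}.
#' @param eps additive offset for the M-value transform.
#' @return A \linkS4class{MethylationMatrix} at stage \code{"raw"}.
#' @export
computeMethylation <- function(object, scale = c("beta", "mvalue"),
                               eps = 0.5) {
    scale <- match.arg(scale)
    sf <- sizeFactors(object)
    if (any(is.na(sf))) {
        warning("size factors not estimated; assuming unit factors")
        sf[] <- 1
    }
    t <- ipCounts(object); c <- inputCounts(object)
    dT <- rep(sf[, "ip"], each = nrow(t))
    dC <- rep(sf[, "input"], each = nrow(t))
    vals <- if (scale == "beta") methylationLevel(t, c, dT, dC)
            else mValue(t, c, dT, dC, eps)
    vals <- matrix(vals, nrow = nrow(t), dimnames = dimnames(t))
    methods::new("MethylationMatrix", values = vals, coverage = t + c,
                 stage = "raw", scale = scale,
                 geneIds = unname(geneIds(object)))
}

#' Quantile normalize methylation levels across conditions
#'
#' Forces every condition's empirical distribution onto their common
#' mean distribution (ties receive the mean reference value of the tied
#' ranks), removing condition-level batch effects. Coverage is passed
#' through untouched.
#'
#' @param object a \linkS4class{MethylationMatrix} with at least two
#'   columns.
#' @return The matrix at stage \code{"quantile_normalized"}.
#' @export
quantileNormalize <- function(object) {
    v <- methLevels(object)
    if (ncol(v) < 2) stop("quantile normalization needs >= 2 columns")
    nv <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(nv) <- dimnames(v)
    methods::initialize(object, values = nv, stage = "quantile_normalized")
}

#' Select sites with strong signal and strong dynamics
#'
#' Two-stage filter: keep the \code{nByMean} sites with the largest
#' average methylation level, then among them the \code{nByVariance}
#' sites with the largest variance across conditions. Ties are broken
#' by input order; the surviving sites keep their original order. The
#' defaults (20000, then 10000) suit transcriptome-wide site sets.
#'
#' @param object a \linkS4class{MethylationMatrix}.
#' @param nByMean,nByVariance stage sizes, \code{nByVariance <=
#'   nByMean}.
#' @return The matrix subset, at stage \code{"selected"}.
#' @export
selectDynamicSites <- function(object, nByMean = 20000, nByVariance = 10000) {
    if (nByMean <= 0) stop("'nByMean' must be positive")
    if (nByVariance > nByMean)
        stop("'nByVariance' must not exceed 'nByMean'")
    v <- methLevels(object)
    n <- nrow(v)
    rm <- rowMeans(v)
    keep1 <- sort(order(-rm, seq_len(n))[seq_len(min(nByMean, n))])
    rv <- apply(v[keep1, , drop = FALSE], 1, stats::var)
    keep2 <- keep1[sort(order(-rv, seq_along(keep1))[
        seq_len(min(nByVariance, length(keep1)))])]
    methods::initialize(object,
        values = v[keep2, , drop = FALSE],
        coverage = methCoverage(object)[keep2, , drop = FALSE],
        geneIds = if (length(object@geneIds)) object@geneIds[keep2]
                  else character(),
        stage = "selected")
}

#' Standardize each site's profile to zero mean and unit variance
#'
#' Row-wise z-scores using the sample (n - 1) standard deviation, so
#' every site contributes equally to distances. A site with a constant
#' profile has no dynamics and no defined z-score; by default this is
#' an error naming the site, but \code{constant = "zero"} centers such
#' rows at 0 instead (useful for small benchmark datasets where fully
#' uncovered sites are expected and are neutral after centering).
#'
#' @param object a \linkS4class{MethylationMatrix}.
#' @param constant \code{"error"} (default) or \code{"zero"}.
#' @return The matrix at stage \code{"standardized"}.
#' @export
standardizeRows <- function(object, constant = c("error", "zero")) {
    constant <- match.arg(constant)
    v <- methLevels(object)
    mu <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    bad <- s == 0
    if (any(bad) && constant == "error")
        stop("constant methylation profile for site(s): ",
             paste(utils::head(rownames(v)[bad], 5), collapse = ", "))
    s[bad] <- 1
    z <- (v - mu) / s
    methods::initialize(object, values = z, stage = "standardized")
}

#' Full quantification pipeline
#'
#' merge replicates -> estimate size factors -> methylation levels ->
#' quantile normalize -> select dynamic sites -> standardize rows.
#' Deterministic: identical inputs give bit-identical outputs.
#'
#' @param object a \linkS4class{MeripCountSet} (replicate columns
#'   allowed).
#' @param scale passed to [computeMethylation()].
#' @param nByMean,nByVariance passed to [selectDynamicSites()].
#' @param constant passed to [standardizeRows()].
#' @return A standardized \linkS4class{MethylationMatrix}.
#' @export
preprocessMethylation <- function(object, scale = "beta",
                                  nByMean = 20000, nByVariance = 10000,
                                  constant = "error") {
    x <- mergeReplicates(object)
    x <- estimateSizeFactors(x)
    m <- computeMethylation(x, scale = scale)
    m <- quantileNormalize(m)
    m <- selectDynamicSites(m, nByMean, nByVariance)
    standardizeRows(m, constant = constant)
}
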