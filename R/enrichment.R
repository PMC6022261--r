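## Biological-significance scoring of modules: one-sided hypergeometric
## term enrichment, a top-m -log10(p) summary score, comparison against
## random modules of the same size, and 2x2 overlap odds ratios.

#' One-sided hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least k annotated genes when n genes are drawn from a
#' background of N genes of which K carry the annotation.
#'
#' @param k observed overlap.
#' @param K annotated genes in the background.
#' @param n module size (genes drawn).
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
hypergeomOverrepP <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
        stop("inconsistent hypergeometric counts")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

## annotation: data.frame(term_id, gene_id) -> named list of gene sets
annotationToList <- function(annotation) {
    if (!all(c("term_id", "gene_id") %in% colnames(annotation)))
        stop("annotation needs 'term_id' and 'gene_id' columns")
    split(as.character(annotation$gene_id),
          as.character(annotation$term_id))
}

#' Biological-significance score of a gene module
#'
#' Tests every annotation term for over-representation in the module
#' against the background by one-sided hypergeometric test, discards
#' terms with more than \code{maxTermCount} background genes (too
#' general to be informative), and sums -log10(p) over the
#' \code{topM} most significant surviving terms (ties broken by term
#' id). Larger scores indicate a more biologically coherent module.
#'
#' @param moduleGenes genes of the module (subset of the background).
#' @param backgroundGenes the background gene universe.
#' @param annotation a term/gene \code{data.frame} (see
#'   [makeAnnotation()] for the schema).
#' @param topM number of top terms summed (default 20).
#' @param maxTermCount background-count cutoff above which a term is
#'   discarded (default 1000).
#' @return A list with \code{score} (the summed -log10 p) and
#'   \code{terms} (per-term data.frame: term_id, k, K, n, N, p,
#'   ordered by p).
#' @export
moduleSignificance <- function(moduleGenes, backgroundGenes, annotation,
                               topM = 20, maxTermCount = 1000) {
    backgroundGenes <- unique(as.character(backgroundGenes))
    moduleGenes <- unique(as.character(moduleGenes))
    if (length(backgroundGenes) == 0) stop("empty background")
    if (!all(moduleGenes %in% backgroundGenes))
        stop("module genes must be a subset of the background")
    sets <- annotationToList(annotation)
    N <- length(backgroundGenes)
    n <- length(moduleGenes)
    rows <- lapply(names(sets), function(tid) {
        inBg <- intersect(sets[[tid]], backgroundGenes)
        K <- length(inBg)
        if (K == 0 || K > maxTermCount) return(NULL)
        k <- length(intersect(inBg, moduleGenes))
        data.frame(term_id = tid, k = k, K = K, n = n, N = N,
                   p = hypergeomOverrepP(k, K, n, N))
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
        return(list(score = 0, terms = data.frame()))
    rows <- rows[order(rows$p, rows$term_id), , drop = FALSE]
    rownames(rows) <- NULL
    top <- utils::head(rows, topM)
    list(score = sum(-log10(top$p)), terms = rows)
}

#' Compare a module's significance against random modules of its size
#'
#' For each repetition, draws a uniformly random site set of the same
#' size from the site universe, maps both site sets to their genes, and
#' scores both with [moduleSignificance()] against the universe's
#' genes as background. Returns the fraction of repetitions in which
#' the module's score strictly exceeds the random module's — near 0.5
#' for a biologically meaningless module, near 1 for a coherent one.
#'
#' @param moduleSites site ids of the module.
#' @param siteUniverse all candidate site ids (superset of the module).
#' @param siteGenes named character vector mapping site id to gene id.
#' @param annotation term/gene \code{data.frame}.
#' @param reps number of random modules (default 100).
#' @param seed seed for the random draws.
#' @param ... passed to [moduleSignificance()].
#' @return Fraction of repetitions won, in [0, 1].
#' @export
compareRandomModules <- function(moduleSites, siteUniverse, siteGenes,
                                 annotation, reps = 100, seed = 1, ...) {
    if (reps < 1) stop("'reps' must be at least 1")
    if (length(moduleSites) > length(siteUniverse))
        stop("module larger than the site universe")
    if (!all(moduleSites %in% siteUniverse))
        stop("module sites must belong to the universe")
    background <- unique(unname(siteGenes[siteUniverse]))
    score <- moduleSignificance(unique(unname(siteGenes[moduleSites])),
                                background, annotation, ...)$score
    set.seed(seed)
    wins <- vapply(seq_len(reps), function(r) {
        rnd <- sample(siteUniverse, length(moduleSites))
        rndScore <- moduleSignificance(unique(unname(siteGenes[rnd])),
                                       background, annotation, ...)$score
        score > rndScore
    }, logical(1))
    mean(wins)
}

#' Overlap odds ratio between a module and a target site set
#'
#' Builds the 2x2 table of membership (in/out module by in/out target)
#' over the site universe, returns the sample odds ratio ad/bc (with
#' the Haldane 0.5 correction when any cell is zero) and a one-sided
#' Fisher exact p-value for enrichment.
#'
#' @param moduleSites,targetSites site id sets, both subsets of
#'   \code{universe}.
#' @param universe all site ids.
#' @return A list with \code{oddsRatio}, \code{p} and \code{table}.
#' @export
overlapOddsRatio <- function(moduleSites, targetSites, universe) {
    universe <- unique(universe)
    if (length(universe) == 0) stop("empty site universe")
    if (!all(moduleSites %in% universe) || !all(targetSites %in% universe))
        stop("site sets must be subsets of the universe")
    inMod <- universe %in% moduleSites
    inTar <- universe %in% targetSites
    a <- sum(inMod & inTar); b <- sum(inMod & !inTar)
    c <- sum(!inMod & inTar); d <- sum(!inMod & !inTar)
    tab <- matrix(c(a, c, b, d), 2, 2,
                  dimnames = list(module = c("in", "out"),
                                  target = c("in", "out")))
    cells <- c(a, b, c, d)
    if (any(cells == 0)) cells <- cells + 0.5
    orr <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    list(oddsRatio = orr, p = p, table = tab)
}
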