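## File formats and the end-to-end pipeline driver. Everything is
## plain TSV/YAML/JSON so runs round-trip across languages.

#' Read a MeRIP-seq count table from TSV
#'
#' Expected schema: one row per site with columns \code{site_id},
#' \code{gene_id}, then paired \code{IP_<sample>} and
#' \code{INPUT_<sample>} integer columns for every sample.
#'
#' @param path TSV file.
#' @param conditionMap optional named character vector mapping sample
#'   ids to conditions (defaults to one condition per sample).
#' @return A \linkS4class{MeripCountSet}.
#' @export
readCountsTSV <- function(path, conditionMap = NULL) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    cols <- colnames(df)
    if (length(cols) < 4 || cols[1] != "site_id" || cols[2] != "gene_id")
        stop("malformed header: expected site_id, gene_id, IP_*/INPUT_* columns")
    ipCols <- grep("^IP_", cols, value = TRUE)
    inCols <- grep("^INPUT_", cols, value = TRUE)
    samples <- sub("^IP_", "", ipCols)
    missingIn <- setdiff(paste0("INPUT_", samples), inCols)
    if (length(missingIn) || length(ipCols) == 0)
        stop("missing count column(s): ",
             paste(c(missingIn, if (!length(ipCols)) "IP_*"), collapse = ", "))
    extraIn <- setdiff(sub("^INPUT_", "", inCols), samples)
    if (length(extraIn))
        stop("missing count column(s): ", paste0("IP_", extraIn, collapse = ", "))
    if (anyDuplicated(df$site_id))
        stop("duplicate site_id: ",
             df$site_id[anyDuplicated(df$site_id)][1])
    countCols <- c(ipCols, paste0("INPUT_", samples))
    for (cc in countCols) {
        x <- df[[cc]]
        if (!is.numeric(x) || any(is.na(x)) || any(x != round(x)))
            stop("non-integer count in column '", cc, "', row ",
                 which(!is.finite(x) | x != round(x))[1])
    }
    ip <- as.matrix(df[, ipCols, drop = FALSE])
    input <- as.matrix(df[, paste0("INPUT_", samples), drop = FALSE])
    dimnames(ip) <- dimnames(input) <- list(df$site_id, samples)
    cond <- if (is.null(conditionMap)) samples else {
        if (!all(samples %in% names(conditionMap)))
            stop("conditionMap missing sample(s): ",
                 paste(setdiff(samples, names(conditionMap)), collapse = ", "))
        unname(conditionMap[samples])
    }
    MeripCountSet(ip, input, condition = cond, geneIds = df$gene_id)
}

#' Write a MeRIP-seq count set as TSV
#'
#' Inverse of [readCountsTSV()] (conditions travel separately).
#'
#' @param object a \linkS4class{MeripCountSet}.
#' @param path output file.
#' @export
writeCountsTSV <- function(object, path) {
    ip <- ipCounts(object); input <- inputCounts(object)
    df <- data.frame(site_id = rownames(ip),
                     gene_id = unname(geneIds(object)),
                     ip, input, check.names = FALSE)
    colnames(df) <- c("site_id", "gene_id",
                      paste0("IP_", colnames(ip)),
                      paste0("INPUT_", colnames(input)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a term/gene annotation table from TSV
#'
#' Columns \code{term_id} and \code{gene_id} required; extra columns
#' (term names, categories) are carried through.
#'
#' @param path TSV file.
#' @return An annotation \code{data.frame}.
#' @export
readAnnotationTSV <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% colnames(df)))
        stop("annotation TSV needs 'term_id' and 'gene_id' columns")
    df
}

#' Attach BED coordinates to a count set
#'
#' Reads a 0-based half-open BED file whose name field holds site ids
#' and stores chrom/start/end in the count set's rowData. Coordinates
#' are carried along, never computed on.
#'
#' @param object a \linkS4class{MeripCountSet}.
#' @param path BED file.
#' @return The object with coordinate columns in its rowData.
#' @export
attachSiteBed <- function(object, path) {
    bed <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4) stop("BED file must have at least 4 columns")
    colnames(bed)[1:4] <- c("chrom", "start", "end", "name")
    idx <- match(rownames(object), bed$name)
    rd <- SummarizedExperiment::rowData(object)
    rd$chrom <- bed$chrom[idx]
    rd$start <- bed$start[idx]
    rd$end <- bed$end[idx]
    SummarizedExperiment::rowData(object) <- rd
    object
}

#' Write a methylation matrix as TSV
#'
#' The header comment line records the processing stage and scale so a
#' reader knows what the numbers are.
#'
#' @param object a \linkS4class{MethylationMatrix}.
#' @param path output file.
#' @export
writeMethylationTSV <- function(object, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# stage=%s scale=%s", object@stage, object@scale),
               con)
    v <- methLevels(object)
    df <- data.frame(site_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to defaults: selection 20000/10000, threshold
#' weighting with alpha = 0.45 and beta = 0.09 (the tuned optimum for
#' 9-condition data), Euclidean metric, complete linkage, k = 5.
#'
#' @param path YAML file.
#' @return A config list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(scale = "beta", nByMean = 20000, nByVariance = 10000,
                     weighting = list(kind = "threshold",
                                      alphaQuantile = 0.45, beta = 0.09,
                                      pairSampleSize = 100000, seed = 1),
                     metric = "euclidean", linkage = "complete", k = 5,
                     writeDistance = FALSE, seed = 1)
    utils::modifyList(defaults, cfg)
}

#' Run the full module-detection pipeline
#'
#' counts -> preprocessing -> weighted distances -> hierarchical
#' clustering into k modules -> per-module gene lists -> (optional)
#' enrichment report. Writes every artifact plus a machine-readable
#' run log (parameters, resolved count threshold, config hash, package
#' version) into \code{outDir}. Reruns with the same config and inputs
#' are bit-identical.
#'
#' @param counts a \linkS4class{MeripCountSet} or path to a counts TSV.
#' @param outDir output directory (created if absent).
#' @param config a config list (see [readRunConfig()]) or path to a
#'   YAML config.
#' @param annotation optional annotation \code{data.frame} or TSV path
#'   for the enrichment report.
#' @return Invisibly, a list with the clustering result, distance
#'   matrix and per-stage artifacts' paths.
#' @export
runPipeline <- function(counts, outDir, config = list(),
                        annotation = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    else config <- utils::modifyList(readRunConfig(textConnectionConfig()),
                                     config)
    if (is.character(counts)) counts <- readCountsTSV(counts,
                                                      config$conditionMap)
    if (is.character(annotation)) annotation <- readAnnotationTSV(annotation)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(config, cfgPath)
    cfgHash <- unname(tools::md5sum(cfgPath))

    zeroFrac <- mean(siteCoverage(counts) == 0)
    if (zeroFrac > 0.5)
        warning(sprintf("%.0f%% of measurements have zero coverage",
                        100 * zeroFrac))

    stage <- "quantify"
    res <- tryCatch({
        meth <- preprocessMethylation(counts, scale = config$scale,
                                      nByMean = config$nByMean,
                                      nByVariance = config$nByVariance,
                                      constant = "zero")
        writeMethylationTSV(meth, file.path(outDir, "methylation.tsv"))

        stage <- "distance"
        w <- config$weighting
        scheme <- WeightingScheme(w$kind, alphaQuantile = w$alphaQuantile,
                                  beta = w$beta,
                                  pairSampleSize = w$pairSampleSize,
                                  seed = w$seed)
        d <- pairwiseDistances(meth, scheme = scheme,
                               metric = config$metric, axis = "sites")
        if (isTRUE(config$writeDistance))
            writeDistanceTSV(d, file.path(outDir, "distance.tsv"))

        stage <- "cluster"
        cl <- hierarchicalCluster(d, k = config$k,
                                  linkage = config$linkage)
        lab <- clusterLabels(cl)
        utils::write.table(
            data.frame(site_id = names(lab), module = lab,
                       gene_id = unname(geneIds(meth))),
            file.path(outDir, "modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        for (mod in sort(unique(lab)))
            writeLines(unique(geneIds(meth)[lab == mod]),
                       file.path(outDir, sprintf("module_%d_genes.txt", mod)))

        enrichPath <- NULL
        if (!is.null(annotation)) {
            stage <- "enrichment"
            bg <- unique(unname(geneIds(meth)))
            rows <- lapply(sort(unique(lab)), function(mod) {
                ms <- moduleSignificance(unique(geneIds(meth)[lab == mod]),
                                         bg, annotation)
                if (nrow(ms$terms) == 0) return(NULL)
                cbind(module = mod, utils::head(ms$terms, 20),
                      score = ms$score)
            })
            rows <- do.call(rbind, rows)
            enrichPath <- file.path(outDir, "enrichment.tsv")
            utils::write.table(rows, enrichPath, sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
        list(meth = meth, dist = d, clustering = cl,
             enrichment = enrichPath)
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })

    log <- list(config = config, config_md5 = cfgHash,
                n_sites_in = nrow(counts),
                n_sites_analyzed = nrow(methLevels(res$meth)),
                resolved_count_threshold = resolvedThreshold(res$dist),
                package_version =
                    as.character(utils::packageVersion("meripModules")))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(res)
}

## empty YAML so readRunConfig defaults apply when config given as list
textConnectionConfig <- function() {
    f <- tempfile(fileext = ".yaml")
    writeLines("{}", f)
    f
}

#' Verify that a pipeline output directory matches its config
#'
#' Recomputes the MD5 of the stored config and compares it with the
#' hash recorded in the run log.
#'
#' @param outDir a directory produced by [runPipeline()].
#' @return TRUE invisibly, or an error describing the mismatch.
#' @export
verifyRun <- function(outDir) {
    log <- jsonlite::read_json(file.path(outDir, "run_log.json"))
    h <- unname(tools::md5sum(file.path(outDir, "config.yaml")))
    if (!identical(h, log$config_md5))
        stop("config hash mismatch: run log records ", log$config_md5,
             " but config.yaml hashes to ", h)
    invisible(TRUE)
}
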