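#' Read a beta-value matrix from TSV
#'
#' Expects probes in rows with the probe id in the first column and a
#' header row of sample ids (the standard array-export orientation).
#' Malformed input is rejected with the offending location rather than
#' coerced: duplicate ids, non-numeric cells and values outside [0,1] are
#' all errors. Probes with more than \code{maxMissing} missing values are
#' dropped with a message.
#'
#' @param path TSV file path
#' @param maxMissing maximum tolerated fraction of NA entries per probe
#' @return numeric matrix, probes x samples
#' @export
readBetaMatrix <- function(path, maxMissing = 0.10) {
    m <- .readNumericMatrix(path, what = "beta")
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("beta value %g outside [0,1] at probe '%s', sample '%s'",
                     m[bad[1, 1], bad[1, 2]],
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    miss <- rowMeans(is.na(m))
    drop <- miss > maxMissing
    if (any(drop)) {
        message(sum(drop), " probes dropped for > ",
                round(100 * maxMissing), "% missing values")
        m <- m[!drop, , drop = FALSE]
    }
    m
}

#' @rdname readBetaMatrix
#' @export
readDetectionP <- function(path) {
    m <- .readNumericMatrix(path, what = "detection p")
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("detection p %g outside [0,1] at probe '%s', sample '%s'",
                     m[bad[1, 1], bad[1, 2]],
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    m
}

.readNumericMatrix <- function(path, what = "value") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = NA)
    if (ncol(df) < 2) stop("expected an id column plus sample columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate probe ids, e.g. '", ids[anyDuplicated(ids)], "'")
    vals <- df[, -1, drop = FALSE]
    if (anyDuplicated(colnames(vals)))
        stop("duplicate sample ids in header")
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (!is.numeric(v)) {
            suspect <- suppressWarnings(as.numeric(v))
            badRow <- which(is.na(suspect) & !is.na(v) &
                            !v %in% c("NA", ""))[1]
            if (!is.na(badRow))
                stop(sprintf("non-numeric %s cell '%s' at probe '%s', sample '%s'",
                             what, v[badRow], ids[badRow],
                             colnames(vals)[j]))
            vals[[j]] <- suspect
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    storage.mode(m) <- "double"
    m
}

#' Write a probe x sample matrix as TSV
#'
#' First column \code{probe_id}, then one column per sample; full
#' precision so write/read round trips are identity.
#'
#' @param m numeric matrix with dimnames
#' @param path output path
#' @export
writeBetaMatrix <- function(m, path) {
    fm <- apply(m, 2, function(v)
        ifelse(is.na(v), "NA", sprintf("%.17g", v)))
    df <- data.frame(probe_id = rownames(m), fm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write a sample sheet CSV
#'
#' Columns: sample_id, group_label, material, grade, mutation_status.
#' @param path CSV path
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group_label")
    if (!all(need %in% names(df)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample sheet")
    if (any(is.na(df$group_label) | df$group_label == ""))
        stop("empty group_label in sample sheet")
    df
}

#' @rdname readSampleSheet
#' @param df data.frame to write
#' @export
writeSampleSheet <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read a probe annotation / manifest CSV
#'
#' Columns: probe_id, chromosome, position (1-based), gene_symbol (may be
#' empty), tss_flag (logical).
#' @param path CSV path
#' @export
readProbeAnnotation <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("probe_id", "chromosome", "position", "gene_symbol",
              "tss_flag")
    if (!all(need %in% names(df)))
        stop("annotation needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
    if (any(df$position < 1)) stop("positions must be >= 1 (1-based)")
    df$tss_flag <- as.logical(df$tss_flag)
    df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>member...}. Duplicate members within a
#' set are collapsed; an empty file yields an empty collection.
#'
#' @param path GMT file path
#' @return list with \code{sets} (named list of unique gene vectors) and
#'   \code{descriptions} (named character)
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT line ", i, " has fewer than 3 fields")
        genes <- unique(f[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (!length(genes)) stop("GMT line ", i, ": empty set")
        sets[[f[1]]] <- genes
        desc[f[1]] <- f[2]
    }
    list(sets = sets, descriptions = desc)
}

#' @rdname readGMT
#' @param collection list as returned by \code{readGMT}
#' @export
writeGMT <- function(collection, path) {
    lines <- vapply(names(collection$sets), function(nm)
        paste(c(nm, collection$descriptions[[nm]] %||% "",
                collection$sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write / read a relatedness graph as GraphML
#'
#' Nodes carry the group label and sample count; edges carry the exact
#' DMP count and bin label; closest-connection annotation edges are
#' flagged with \code{is_closest = TRUE} so a generic reader can
#' distinguish them from binned edges.
#'
#' @param graph a \linkS4class{RelatednessGraph}
#' @param path output path
#' @export
writeGraphML <- function(graph, path) {
    stopifnot(is(graph, "RelatednessGraph"))
    ed <- rbind(
        if (nrow(graph@edges)) cbind(graph@edges[, c("from", "to")],
            count = graph@edges$count, bin = graph@edges$bin,
            is_closest = FALSE),
        if (nrow(graph@closest)) cbind(graph@closest[, c("from", "to")],
            count = graph@closest$count, bin = "closest_connection",
            is_closest = TRUE))
    g <- igraph::graph_from_data_frame(
        d = if (is.null(ed)) data.frame(from = character(),
                                        to = character()) else ed,
        directed = FALSE,
        vertices = data.frame(name = graph@nodes$label,
                              n_samples = graph@nodes$nSamples))
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' @rdname writeGraphML
#' @return \code{readGraphML}: an igraph object with the stored node and
#'   edge attributes
#' @export
readGraphML <- function(path) {
    igraph::read_graph(path, format = "graphml")
}

#' Write a generated cohort to a directory in interchange formats
#'
#' Beta and detection-p matrices as TSV, sample sheet and probe
#' annotation as CSV, ground truth as JSON.
#'
#' @param cohort list from \code{\link{generateCohort}}
#' @param dir output directory (created if needed)
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    me <- cohort$experiment
    writeBetaMatrix(getBeta(me), file.path(dir, "beta.tsv"))
    if (!is.null(getDetP(me)))
        writeBetaMatrix(getDetP(me), file.path(dir, "detection_p.tsv"))
    writeSampleSheet(sampleSheet(me), file.path(dir, "sample_sheet.csv"))
    utils::write.csv(probeAnnotation(me),
                     file.path(dir, "probe_annotation.csv"),
                     row.names = FALSE)
    gt <- cohort$groundTruth
    gt$groupMeans <- NULL    # bulky; reproducible from the config
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname writeCohort
#' @return \code{readCohort}: list with \code{experiment} and
#'   \code{groundTruth} (NULL if no JSON present)
#' @export
readCohort <- function(dir) {
    beta <- readBetaMatrix(file.path(dir, "beta.tsv"))
    detP <- NULL
    if (file.exists(file.path(dir, "detection_p.tsv")))
        detP <- readDetectionP(file.path(dir, "detection_p.tsv"))
    sheet <- readSampleSheet(file.path(dir, "sample_sheet.csv"))
    anno <- readProbeAnnotation(file.path(dir, "probe_annotation.csv"))
    anno <- anno[match(rownames(beta), anno$probe_id), ]
    gt <- NULL
    gtPath <- file.path(dir, "ground_truth.json")
    if (file.exists(gtPath))
        gt <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    list(experiment = MethylExperiment(beta, detP = detP,
                                       sampleSheet = sheet,
                                       probeAnnotation = anno),
         groundTruth = gt)
}
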