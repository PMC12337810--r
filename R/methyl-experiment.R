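#' Construct a MethylExperiment
#'
#' Bundle a beta-value matrix with an optional detection p-value matrix,
#' sample sheet and probe annotation into a validated
#' \linkS4class{MethylExperiment}.
#'
#' @param beta numeric matrix, probes in rows, samples in columns, values
#'   in [0,1] (NA allowed for missing entries)
#' @param detP optional numeric matrix of detection p-values, same
#'   dimensions and dimnames as \code{beta}
#' @param sampleSheet optional data.frame with one row per sample
#'   (matched to \code{colnames(beta)} by its \code{sample_id} column, or
#'   by row order if absent)
#' @param probeAnnotation optional data.frame with one row per probe
#'   (matched by \code{probe_id} column, or by row order)
#' @return a \linkS4class{MethylExperiment}
#' @examples
#' b <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
#' me <- MethylExperiment(b)
#' dim(me)
#' @export
MethylExperiment <- function(beta, detP = NULL, sampleSheet = NULL,
                             probeAnnotation = NULL) {
    if (!is.matrix(beta) || !is.numeric(beta))
        stop("'beta' must be a numeric matrix")
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("'beta' needs probe rownames and sample colnames")
    assays <- list(beta = beta)
    if (!is.null(detP)) {
        if (!identical(dim(detP), dim(beta)))
            stop("'detP' dimensions must match 'beta'")
        dimnames(detP) <- dimnames(beta)
        assays$detP <- detP
    }
    cd <- if (is.null(sampleSheet)) {
        DataFrame(row.names = colnames(beta))
    } else {
        ss <- as.data.frame(sampleSheet)
        if ("sample_id" %in% names(ss)) {
            if (!setequal(ss$sample_id, colnames(beta)))
                stop("sampleSheet sample_id does not match beta columns")
            ss <- ss[match(colnames(beta), ss$sample_id), , drop = FALSE]
        } else if (nrow(ss) != ncol(beta)) {
            stop("sampleSheet rows must match beta columns")
        }
        rownames(ss) <- colnames(beta)
        DataFrame(ss)
    }
    rd <- if (is.null(probeAnnotation)) {
        DataFrame(row.names = rownames(beta))
    } else {
        an <- as.data.frame(probeAnnotation)
        if ("probe_id" %in% names(an)) {
            missing <- setdiff(rownames(beta), an$probe_id)
            if (length(missing))
                stop("probeAnnotation missing probes, e.g. ",
                     paste(utils::head(missing, 3), collapse = ", "))
            an <- an[match(rownames(beta), an$probe_id), , drop = FALSE]
        } else if (nrow(an) != nrow(beta)) {
            stop("probeAnnotation rows must match beta rows")
        }
        rownames(an) <- rownames(beta)
        DataFrame(an)
    }
    se <- SummarizedExperiment(assays = assays, colData = cd, rowData = rd)
    new("MethylExperiment", se)
}

#' Access the beta-value and detection p-value assays
#'
#' @param object a \linkS4class{MethylExperiment}
#' @return \code{getBeta} the probe x sample beta matrix; \code{getDetP}
#'   the detection p-value matrix or NULL if absent.
#' @export
setGeneric("getBeta", function(object) standardGeneric("getBeta"))

#' @rdname getBeta
#' @export
setMethod("getBeta", "MethylExperiment",
          function(object) assay(object, "beta"))

#' @rdname getBeta
#' @export
setGeneric("getDetP", function(object) standardGeneric("getDetP"))

#' @rdname getBeta
#' @export
setMethod("getDetP", "MethylExperiment", function(object)
    if ("detP" %in% assayNames(object)) assay(object, "detP") else NULL)

#' Sample sheet and probe annotation accessors
#'
#' @param object a \linkS4class{MethylExperiment}
#' @return plain data.frames (the colData / rowData with a
#'   \code{sample_id} / \code{probe_id} column ensured).
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "MethylExperiment", function(object) {
    df <- as.data.frame(colData(object))
    if (!"sample_id" %in% names(df))
        df <- cbind(sample_id = colnames(object), df)
    df$sample_id <- colnames(object)
    rownames(df) <- NULL
    df
})

#' @rdname sampleSheet
#' @export
setGeneric("probeAnnotation",
           function(object) standardGeneric("probeAnnotation"))

#' @rdname sampleSheet
#' @export
setMethod("probeAnnotation", "MethylExperiment", function(object) {
    df <- as.data.frame(rowData(object))
    if (!"probe_id" %in% names(df))
        df <- cbind(probe_id = rownames(object), df)
    df$probe_id <- rownames(object)
    rownames(df) <- NULL
    df
})

setMethod("show", "MethylExperiment", function(object) {
    cat("MethylExperiment:", nrow(object), "probes x", ncol(object),
        "samples\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    ss <- colData(object)
    if ("group_label" %in% names(ss)) {
        tab <- table(ss$group_label)
        cat("  groups:", length(tab), "(",
            paste(utils::head(names(tab), 5), collapse = ", "),
            if (length(tab) > 5) "..." else "", ")\n")
    }
})
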