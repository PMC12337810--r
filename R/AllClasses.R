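#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MethylExperiment: beta values with companion detection p-values
#'
#' An extension of \linkS4class{SummarizedExperiment} holding a probe x
#' sample matrix of methylation beta values (assay \code{"beta"}) and,
#' optionally, a same-shaped matrix of detection p-values (assay
#' \code{"detP"}). Probe annotation (chromosome, position, gene symbol,
#' TSS-region flag) lives in \code{rowData}; the sample sheet (group label,
#' material, grade, mutation status) lives in \code{colData}.
#'
#' Validity requires unique probe and sample identifiers, all beta values
#' finite in [0,1] or NA, and detection p-values (when present) in [0,1]
#' with matching dimensions.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @seealso \code{\link{MethylExperiment}} (constructor),
#'   \code{\link{getBeta}}, \code{\link{getDetP}}
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

.validMethylExperiment <- function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (anyDuplicated(rownames(b)))
            msg <- c(msg, "duplicate probe ids")
        if (anyDuplicated(colnames(b)))
            msg <- c(msg, "duplicate sample ids")
        bad <- !is.na(b) & (!is.finite(b) | b < 0 | b > 1)
        if (any(bad))
            msg <- c(msg, sprintf("%d beta values outside [0,1]", sum(bad)))
    }
    if ("detP" %in% assayNames(object)) {
        p <- assay(object, "detP")
        if (!identical(dim(p), dim(assay(object, "beta"))))
            msg <- c(msg, "detP dimensions do not match beta")
        bad <- !is.na(p) & (p < 0 | p > 1)
        if (any(bad))
            msg <- c(msg, sprintf("%d detection p-values outside [0,1]",
                                  sum(bad)))
    }
    if (length(msg)) msg else TRUE
}
setValidity("MethylExperiment", .validMethylExperiment)

#' Pairwise differential methylation counts over sample groups
#'
#' Result container of \code{\link{pairwiseDMPCounts}}: a symmetric
#' group x group matrix of DMP counts (diagonal zero), the per-pair DMP
#' tables, the thresholds used, and any groups skipped for having fewer
#' than two samples.
#'
#' @slot counts symmetric numeric matrix, group labels as dimnames
#' @slot sets named list, one DMP table per unordered pair ("A|B")
#' @slot thresholds list with \code{pAdjMax} and \code{absLfcMin}
#' @slot skipped character, group labels excluded from the analysis
#' @seealso \code{\link{dmpCounts}}, \code{\link{dmpSet}},
#'   \code{\link{buildNetwork}}
#' @export
setClass("PairwiseDMP",
    representation(counts = "matrix", sets = "list", thresholds = "list",
                   skipped = "character"))

setValidity("PairwiseDMP", function(object) {
    m <- object@counts
    msg <- character()
    if (!isSymmetric(unname(m)))
        msg <- c(msg, "count matrix must be symmetric")
    if (any(diag(m) != 0))
        msg <- c(msg, "diagonal must be zero")
    if (any(m < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "count matrix needs matching group dimnames")
    if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' Sample x sample co-clustering frequencies from repeated subsampled
#' hierarchical clusterings. Entry (i,j) is the number of resamples in
#' which i and j fell in the same cluster divided by the number of
#' resamples in which both were drawn; pairs never co-drawn are NA. The
#' diagonal is 1 by convention.
#'
#' @slot consensus numeric matrix in [0,1] (NA where never co-drawn)
#' @slot codraws integer matrix of co-draw counts
#' @slot B number of resampling iterations
#' @slot subsampleFraction fraction of samples drawn per iteration
#' @slot k number of clusters at each cut
#' @slot distance,linkage base clusterer settings
#' @slot seed RNG seed used
#' @seealso \code{\link{consensusCluster}}, \code{\link{consensusDegreeTest}}
#' @export
setClass("ConsensusResult",
    representation(consensus = "matrix", codraws = "matrix",
                   B = "numeric", subsampleFraction = "numeric",
                   k = "numeric", distance = "character",
                   linkage = "character", seed = "numeric"))

setValidity("ConsensusResult", function(object) {
    m <- object@consensus
    msg <- character()
    if (!isSymmetric(unname(m))) msg <- c(msg, "consensus must be symmetric")
    v <- m[!is.na(m)]
    if (any(v < 0 | v > 1)) msg <- c(msg, "consensus values outside [0,1]")
    if (any(diag(m) != 1)) msg <- c(msg, "diagonal must be 1")
    if (length(msg)) msg else TRUE
})

#' Group relatedness network
#'
#' Graph over sample groups in which an edge between two groups is drawn
#' when their pairwise DMP count falls inside one of the configured count
#' bins; fewer DMPs mean stronger similarity. Groups left without any
#' qualifying edge can carry "closest connection" annotations naming their
#' minimum-count partner with the exact count.
#'
#' @slot nodes data.frame with \code{label} and \code{nSamples}
#' @slot edges data.frame with \code{from}, \code{to}, \code{count},
#'   \code{bin}
#' @slot closest data.frame with \code{from}, \code{to}, \code{count}
#'   (annotation edges for otherwise isolated groups)
#' @slot bins the bin scheme data.frame used (see \code{\link{binScheme}})
#' @seealso \code{\link{buildNetwork}}, \code{\link{annotateClosest}},
#'   \code{\link{writeGraphML}}
#' @export
setClass("RelatednessGraph",
    representation(nodes = "data.frame", edges = "data.frame",
                   closest = "data.frame", bins = "data.frame"))

setValidity("RelatednessGraph", function(object) {
    msg <- character()
    if (nrow(object@edges) &&
        !all(object@edges$from %in% object@nodes$label &
             object@edges$to %in% object@nodes$label))
        msg <- c(msg, "edge endpoints must be nodes")
    if (nrow(object@edges) && any(object@edges$count >=
            max(object@bins$upper)))
        msg <- c(msg, "edge count at or beyond the last bin upper bound")
    if (length(msg)) msg else TRUE
})
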