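#' Direction-labelled gene lists from differentially methylated TSS probes
#'
#' Restricts a DMP table to probes flagged as lying in a
#' transcription-start-site region, maps them to genes, and labels each
#' gene by the sign of its mean methylation difference: genes whose TSS
#' probes are hypermethylated in the lesion (positive delta in
#' lesion-vs-normal orientation) are called \emph{inhibited}, genes with
#' hypomethylated TSS probes \emph{activated}. Genes whose TSS probes
#' disagree in sign are resolved by the sign of the mean delta and
#' reported as conflicting.
#'
#' The contrast orientation must be explicit: with
#' \code{orientation = "B-A"} (the \code{\link{moderatedT}} convention)
#' positive delta means higher methylation in group B, so the caller
#' decides which group is the lesion; \code{flip = TRUE} reverses the
#' interpretation.
#'
#' @param dmps DMP table from \code{\link{callDMPs}} (needs
#'   \code{probe_id} and \code{delta})
#' @param annotation probe annotation data.frame with \code{probe_id},
#'   \code{gene_symbol}, \code{tss_flag}
#' @param flip reverse the contrast orientation before labelling
#' @return list of class \code{"DirectionalGeneLists"}: \code{activated},
#'   \code{inhibited} (gene vectors), \code{conflicting} (genes with
#'   mixed-sign probes), \code{universe} (all genes with >= 1 TSS probe
#'   in the annotation)
#' @export
dmpsToGeneLists <- function(dmps, annotation, flip = FALSE) {
    missing <- setdiff(dmps$probe_id, annotation$probe_id)
    if (length(missing))
        stop("annotation missing DMP probes, e.g. ",
             paste(utils::head(missing, 3), collapse = ", "))
    ann <- annotation[match(dmps$probe_id, annotation$probe_id), ]
    keep <- ann$tss_flag & !is.na(ann$gene_symbol) &
            nzchar(ann$gene_symbol)
    genes <- ann$gene_symbol[keep]
    delta <- dmps$delta[keep] * if (flip) -1 else 1
    meanDelta <- tapply(delta, genes, mean)
    signs <- tapply(sign(delta), genes, function(s) length(unique(s)))
    conflicting <- names(signs)[signs > 1]
    if (length(conflicting))
        message(length(conflicting),
                " genes with conflicting TSS probe directions; ",
                "assigned by mean delta sign")
    uniAnn <- annotation[annotation$tss_flag &
                         !is.na(annotation$gene_symbol) &
                         nzchar(annotation$gene_symbol), ]
    structure(list(
        activated = sort(names(meanDelta)[meanDelta < 0]),
        inhibited = sort(names(meanDelta)[meanDelta > 0]),
        conflicting = sort(conflicting),
        universe = sort(unique(uniAnn$gene_symbol))),
        class = "DirectionalGeneLists")
}

#' @export
print.DirectionalGeneLists <- function(x, ...) {
    cat("DirectionalGeneLists:", length(x$activated), "activated,",
        length(x$inhibited), "inhibited (",
        length(x$conflicting), "conflicting ) of",
        length(x$universe), "TSS genes\n")
    invisible(x)
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' One-sided upper-tail hypergeometric test of each set's overlap with
#' the query, using the supplied universe as the sampling frame (sets
#' are intersected with the universe before testing), BH-adjusted across
#' sets. The p-value includes the observed overlap:
#' P(X >= k) for k = |query ∩ set|.
#'
#' @param query character vector of genes (must lie in \code{universe})
#' @param universe character vector, the sampling frame (e.g. all genes
#'   with >= 1 TSS probe on the array)
#' @param collection gene-set collection from \code{\link{readGMT}} or a
#'   named list of gene vectors
#' @param direction optional label ("activated"/"inhibited") copied into
#'   the result
#' @return data.frame: \code{set}, \code{overlap}, \code{setSize} (in
#'   universe), \code{querySize}, \code{universeSize}, \code{p},
#'   \code{q}, \code{direction}
#' @export
hypergeometricEnrich <- function(query, universe, collection,
                                 direction = NA_character_) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query genes outside the universe, e.g. ",
             paste(utils::head(setdiff(query, universe), 3),
                   collapse = ", "))
    sets <- if (is.list(collection) && !is.null(collection$sets))
        collection$sets else collection
    if (!length(query)) {
        warning("empty query; no enrichment computed")
        return(data.frame(set = character(), overlap = integer(),
                          setSize = integer(), querySize = integer(),
                          universeSize = integer(), p = numeric(),
                          q = numeric(), direction = character()))
    }
    N <- length(universe); q <- length(query)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], universe)
        k <- length(intersect(s, query))
        # P(X >= k), X ~ Hypergeom(white = |set|, black = N - |set|,
        # drawn = |query|)
        p <- stats::phyper(k - 1, length(s), N - length(s), q,
                           lower.tail = FALSE)
        data.frame(set = nm, overlap = k, setSize = length(s),
                   querySize = q, universeSize = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$q <- bhAdjust(out$p)
    out$direction <- direction
    out[order(out$p), ]
}
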