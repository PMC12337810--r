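#' DMP-count bin scheme for the relatedness network
#'
#' The published scheme draws an edge between two groups when their DMP
#' count falls into one of five bins — 0, 1-999, 1,000-4,999,
#' 5,000-9,999, 10,000-14,999 — and no edge at 15,000 or more (fewer
#' DMPs = stronger similarity, so the 0-count bin is the strongest tie).
#'
#' @param lower,upper integer vectors of inclusive lower / exclusive
#'   upper bounds
#' @param label bin labels
#' @return data.frame with \code{lower}, \code{upper}, \code{label};
#'   validated to be disjoint, ordered and non-overlapping
#' @export
binScheme <- function(lower = c(0, 1, 1000, 5000, 10000),
                      upper = c(1, 1000, 5000, 10000, 15000),
                      label = c("0", "1-999", "1000-4999", "5000-9999",
                                "10000-14999")) {
    stopifnot(length(lower) == length(upper),
              length(lower) == length(label))
    if (any(upper <= lower)) stop("each bin needs upper > lower")
    if (is.unsorted(lower, strictly = TRUE) ||
        any(utils::head(upper, -1) > utils::tail(lower, -1)))
        stop("bins must be ordered and non-overlapping")
    data.frame(lower = as.integer(lower), upper = as.integer(upper),
               label = label, stringsAsFactors = FALSE)
}

.binOf <- function(count, bins) {
    hit <- which(count >= bins$lower & count < bins$upper)
    if (length(hit)) bins$label[hit[1]] else NA_character_
}

#' Build the group relatedness network from pairwise DMP counts
#'
#' One node per group; one edge per group pair whose DMP count falls
#' inside a bin of \code{bins}, carrying the exact count and the bin
#' label. Pairs at or beyond the last bin's upper bound get no edge —
#' such groups may end up disconnected and can then be annotated with
#' their closest connection (\code{\link{annotateClosest}}).
#'
#' @param counts a \linkS4class{PairwiseDMP} or a symmetric named count
#'   matrix
#' @param bins a bin scheme from \code{\link{binScheme}}
#' @param nSamples optional named vector of per-group sample counts for
#'   the node table (taken from the matrix attributes if absent)
#' @return a \linkS4class{RelatednessGraph}
#' @export
buildNetwork <- function(counts, bins = binScheme(), nSamples = NULL) {
    cm <- if (is(counts, "PairwiseDMP")) dmpCounts(counts) else counts
    if (!isSymmetric(unname(cm)))
        stop("count matrix must be symmetric")
    bins <- binScheme(bins$lower, bins$upper, bins$label)  # re-validate
    labels <- rownames(cm)
    nodes <- data.frame(label = labels,
                        nSamples = if (is.null(nSamples)) NA_integer_
                                   else unname(nSamples[labels]),
                        stringsAsFactors = FALSE)
    ed <- list()
    for (a in seq_len(length(labels) - 1))
        for (b in seq(a + 1, length(labels))) {
            cnt <- cm[a, b]
            lab <- .binOf(cnt, bins)
            if (!is.na(lab))
                ed[[length(ed) + 1]] <- data.frame(
                    from = labels[a], to = labels[b], count = cnt,
                    bin = lab, stringsAsFactors = FALSE)
        }
    edges <- if (length(ed)) do.call(rbind, ed) else
        data.frame(from = character(), to = character(),
                   count = numeric(), bin = character(),
                   stringsAsFactors = FALSE)
    new("RelatednessGraph", nodes = nodes, edges = edges,
        closest = data.frame(from = character(), to = character(),
                             count = numeric(),
                             stringsAsFactors = FALSE),
        bins = bins)
}

#' Annotate disconnected groups with their closest connection
#'
#' For every node without a qualifying (binned) edge, records the
#' partner group with the minimum DMP count and the exact count; ties
#' keep all tied partners.
#'
#' @param graph a \linkS4class{RelatednessGraph} built from
#'   \code{counts}
#' @param counts the same \linkS4class{PairwiseDMP} or count matrix the
#'   graph was built from
#' @return the graph with its \code{closest} table filled in
#' @export
annotateClosest <- function(graph, counts) {
    stopifnot(is(graph, "RelatednessGraph"))
    cm <- if (is(counts, "PairwiseDMP")) dmpCounts(counts) else counts
    connected <- unique(c(graph@edges$from, graph@edges$to))
    isolated <- setdiff(graph@nodes$label, connected)
    rows <- list()
    for (g in isolated) {
        row <- cm[g, setdiff(colnames(cm), g)]
        best <- names(row)[row == min(row)]
        for (p in sort(best))
            rows[[length(rows) + 1]] <- data.frame(
                from = g, to = p, count = unname(min(row)),
                stringsAsFactors = FALSE)
    }
    graph@closest <- if (length(rows)) do.call(rbind, rows) else
        graph@closest
    graph
}

#' Most closely related group by DMP count
#'
#' Argmin over the other groups of the pairwise DMP count — the
#' "closest entity" of a group in the relatedness sense. Deterministic
#' tie-break: the lexicographically first label.
#'
#' @param counts a \linkS4class{PairwiseDMP} or symmetric named matrix
#' @param group group label
#' @return list with \code{group} (nearest label) and \code{count}
#' @export
nearestEntity <- function(counts, group) {
    cm <- if (is(counts, "PairwiseDMP")) dmpCounts(counts) else counts
    if (!group %in% rownames(cm)) stop("unknown group: ", group)
    row <- cm[group, setdiff(colnames(cm), group)]
    best <- sort(names(row)[row == min(row)])[1]
    list(group = best, count = unname(cm[group, best]))
}

#' Flat edge-list export of a relatedness graph
#'
#' @param graph a \linkS4class{RelatednessGraph}
#' @param path TSV output path (columns: group_a, group_b, count, bin,
#'   is_closest_annotation)
#' @export
writeEdgeList <- function(graph, path) {
    stopifnot(is(graph, "RelatednessGraph"))
    tab <- rbind(
        if (nrow(graph@edges)) data.frame(
            group_a = graph@edges$from, group_b = graph@edges$to,
            count = graph@edges$count, bin = graph@edges$bin,
            is_closest_annotation = FALSE, stringsAsFactors = FALSE),
        if (nrow(graph@closest)) data.frame(
            group_a = graph@closest$from, group_b = graph@closest$to,
            count = graph@closest$count, bin = "closest_connection",
            is_closest_annotation = TRUE, stringsAsFactors = FALSE))
    if (is.null(tab))
        tab <- data.frame(group_a = character(), group_b = character(),
                          count = numeric(), bin = character(),
                          is_closest_annotation = logical())
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

setMethod("show", "RelatednessGraph", function(object) {
    cat("RelatednessGraph:", nrow(object@nodes), "groups,",
        nrow(object@edges), "binned edges,", nrow(object@closest),
        "closest-connection annotations\n")
    if (nrow(object@edges)) {
        tab <- table(factor(object@edges$bin,
                            levels = object@bins$label))
        for (l in names(tab))
            if (tab[[l]]) cat("  bin", l, ":", tab[[l]], "edges\n")
    }
})
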