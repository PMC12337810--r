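#' t-SNE embedding of samples
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of the
#' samples of a (typically top-variance-restricted) beta matrix. Samples
#' are rows of the internal data matrix; initialisation uses PCA to 50
#' components for stability and the seed is mandatory so embeddings are
#' reproducible.
#'
#' @param m probe x sample matrix (e.g. restricted to a
#'   \code{\link{selectTopSD}} subset) or \linkS4class{MethylExperiment}
#' @param perplexity t-SNE perplexity; requires
#'   \code{n_samples > 3 * perplexity}
#' @param seed integer RNG seed (required)
#' @param maxIter gradient-descent iterations
#' @return data.frame of class \code{"Embedding"}: \code{sample_id},
#'   \code{x}, \code{y}; parameters attached as attribute \code{params}
#' @export
tsneEmbed <- function(m, perplexity = 30, seed, maxIter = 1000) {
    if (is(m, "MethylExperiment")) m <- getBeta(m)
    if (missing(seed)) stop("an explicit seed is required")
    n <- ncol(m)
    if (n <= 3 * perplexity)
        stop("perplexity ", perplexity, " too large for ", n,
             " samples; need n > 3 * perplexity (try perplexity <= ",
             floor((n - 1) / 3), ")")
    set.seed(seed)
    x <- t(m)
    fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                        max_iter = maxIter, pca = TRUE,
                        initial_dims = min(50, n - 1, nrow(m)),
                        check_duplicates = FALSE, verbose = FALSE)
    out <- data.frame(sample_id = colnames(m), x = fit$Y[, 1],
                      y = fit$Y[, 2], stringsAsFactors = FALSE)
    attr(out, "params") <- list(perplexity = perplexity, seed = seed,
                                maxIter = maxIter)
    class(out) <- c("Embedding", "data.frame")
    out
}

#' k-nearest-neighbour label purity of an embedding
#'
#' For each sample, the fraction of its k nearest neighbours (Euclidean,
#' in the embedding) sharing its label; the mean over samples. A
#' quantitative stand-in for "groups visually separate in the t-SNE".
#'
#' @param embedding data.frame with \code{x}, \code{y} (and
#'   \code{sample_id} aligned with \code{labels})
#' @param labels character vector of group labels, one per sample
#' @param k neighbourhood size
#' @return mean purity in [0,1]
#' @export
knnPurity <- function(embedding, labels, k = 10) {
    stopifnot(nrow(embedding) == length(labels), k >= 1,
              k < nrow(embedding))
    xy <- as.matrix(embedding[, c("x", "y")])
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    mean(vapply(seq_len(nrow(d)), function(i) {
        nn <- order(d[i, ])[seq_len(k)]
        mean(labels[nn] == labels[i])
    }, 0))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples with 1 - Pearson correlation
#' distance and average linkage by default (the conventional settings
#' for methylation-classifier landscapes). Returns a base \code{hclust}
#' tree; cut with \code{\link[stats]{cutree}}.
#'
#' @param m probe x sample matrix or \linkS4class{MethylExperiment}
#' @param distance \code{"pearson"} (1 - correlation) or
#'   \code{"euclidean"}
#' @param linkage an \code{hclust} agglomeration method
#' @return an \code{hclust} object over samples
#' @export
hierarchicalCluster <- function(m, distance = c("pearson", "euclidean"),
                                linkage = "average") {
    if (is(m, "MethylExperiment")) m <- getBeta(m)
    distance <- match.arg(distance)
    if (ncol(m) < 2) stop("need at least 2 samples")
    if (anyNA(m)) stop("matrix contains missing values; filter first")
    d <- .sampleDist(m, distance)
    stats::hclust(d, method = linkage)
}

.sampleDist <- function(m, distance) {
    if (distance == "pearson") {
        stats::as.dist(1 - stats::cor(m))
    } else {
        stats::dist(t(m))
    }
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} object
#' @param path output path
#' @export
writeNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Agglomerative consensus clustering
#'
#' Repeats hierarchical clustering on B random subsamples of the samples
#' (without replacement, fraction \code{subsampleFraction}), cuts each
#' tree at k clusters, and records for every sample pair the fraction of
#' co-draws in which the two samples co-clustered. Pairs never drawn
#' together are reported as NA (missing), not 0.
#'
#' @param m probe x sample matrix (typically the top-variance subset) or
#'   \linkS4class{MethylExperiment}
#' @param k number of clusters at each cut
#' @param B resampling iterations (>= 10)
#' @param subsampleFraction fraction of samples per draw, in (0.5, 1)
#' @param seed integer RNG seed
#' @param distance,linkage base clusterer settings
#'   (see \code{\link{hierarchicalCluster}})
#' @return a \linkS4class{ConsensusResult}
#' @export
consensusCluster <- function(m, k, B = 500, subsampleFraction = 0.8,
                             seed = 1, distance = "pearson",
                             linkage = "average") {
    if (is(m, "MethylExperiment")) m <- getBeta(m)
    stopifnot(B >= 10)
    if (subsampleFraction <= 0.5 || subsampleFraction >= 1)
        stop("subsampleFraction must be in (0.5, 1)")
    n <- ncol(m)
    nSub <- floor(subsampleFraction * n)
    if (k > nSub)
        stop("k = ", k, " exceeds the subsample size ", nSub)
    set.seed(seed)
    ids <- colnames(m)
    co <- matrix(0, n, n, dimnames = list(ids, ids))
    draws <- matrix(0, n, n, dimnames = list(ids, ids))
    for (b in seq_len(B)) {
        idx <- sort(sample.int(n, nSub))
        sub <- m[, idx, drop = FALSE]
        hc <- stats::hclust(.sampleDist(sub, distance), method = linkage)
        cl <- stats::cutree(hc, k = k)
        same <- outer(cl, cl, "==")
        co[idx, idx] <- co[idx, idx] + same
        draws[idx, idx] <- draws[idx, idx] + 1
    }
    cons <- ifelse(draws > 0, co / draws, NA)
    diag(cons) <- 1
    new("ConsensusResult", consensus = cons,
        codraws = matrix(as.integer(draws), n, n,
                         dimnames = dimnames(draws)),
        B = B, subsampleFraction = subsampleFraction, k = k,
        distance = distance, linkage = linkage, seed = seed)
}

#' Access the consensus matrix
#'
#' @param object a \linkS4class{ConsensusResult}
#' @return the symmetric sample x sample co-clustering frequency matrix
#' @export
setGeneric("consensusMatrix", function(object)
    standardGeneric("consensusMatrix"))

#' @rdname consensusMatrix
#' @export
setMethod("consensusMatrix", "ConsensusResult",
          function(object) object@consensus)

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult:", nrow(object@consensus), "samples, B =",
        object@B, ", k =", object@k, "\n")
    cat("  subsample", object@subsampleFraction, ", distance",
        object@distance, "/", object@linkage, "\n")
    off <- object@consensus[upper.tri(object@consensus)]
    cat(sprintf("  mean off-diagonal consensus: %.3f (%d pairs never co-drawn)\n",
                mean(off, na.rm = TRUE), sum(is.na(off))))
})

#' Consensus-degree comparison of a reference group against all others
#'
#' Tests, for each non-reference group g, whether the consensus values
#' among reference samples (within-reference, upper triangle only)
#' differ from the consensus values between reference samples and
#' samples of g, using the two-sided Mann-Whitney test, with BH
#' adjustment across groups. A non-significant result means the samples
#' of g co-cluster with the reference as strongly as the reference
#' co-clusters with itself — the signature of a sibling entity.
#'
#' @param cons a \linkS4class{ConsensusResult}
#' @param sheet sample sheet with \code{sample_id}, \code{group_label}
#' @param referenceGroups one or more group labels forming the reference
#' @return data.frame: \code{group}, \code{nWithin}, \code{nBetween},
#'   \code{statistic} (Mann-Whitney U), \code{p}, \code{q} (BH),
#'   \code{significant} at alpha = 0.05 on q
#' @export
consensusDegreeTest <- function(cons, sheet, referenceGroups) {
    stopifnot(is(cons, "ConsensusResult"))
    cm <- cons@consensus
    if (!all(referenceGroups %in% sheet$group_label))
        stop("reference group not present in sample sheet")
    refIds <- sheet$sample_id[sheet$group_label %in% referenceGroups]
    refIds <- intersect(refIds, rownames(cm))
    if (length(refIds) < 2) stop("reference needs at least 2 samples")
    sub <- cm[refIds, refIds]
    within <- sub[upper.tri(sub)]
    within <- within[!is.na(within)]
    others <- setdiff(unique(sheet$group_label), referenceGroups)
    rows <- list()
    for (g in others) {
        gIds <- intersect(sheet$sample_id[sheet$group_label == g],
                          rownames(cm))
        if (length(gIds) < 2) {
            warning("group ", g, " has < 2 samples; skipped")
            next
        }
        between <- as.vector(cm[refIds, gIds])
        between <- between[!is.na(between)]
        wt <- suppressWarnings(
            stats::wilcox.test(within, between, exact = FALSE))
        # all-tied samples give a degenerate normal approximation (NaN);
        # identical distributions, so p = 1
        pv <- if (is.na(wt$p.value)) 1 else wt$p.value
        rows[[g]] <- data.frame(group = g, nWithin = length(within),
                                nBetween = length(between),
                                statistic = unname(wt$statistic),
                                p = pv,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$q <- bhAdjust(out$p)
    out$significant <- out$q < 0.05
    out
}
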