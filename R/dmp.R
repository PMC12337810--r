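#' Moderated two-group differential methylation statistic
#'
#' Per-probe two-sample comparison with empirical-Bayes shrinkage of the
#' pooled within-group variances toward a common prior. For probe g with
#' pooled variance s2_g on d = nA + nB - 2 residual degrees of freedom,
#' the prior (d0, s0^2) is fitted by method of moments on the log
#' variances (matching the mean and variance of log s2 under a scaled
#' F distribution, via a Newton inversion of the trigamma function), and
#' the posterior variance is
#' \deqn{\tilde s^2_g = (d0 s0^2 + d s2_g) / (d0 + d),}
#' giving the moderated statistic
#' \deqn{t_g = \Delta_g / (\tilde s_g \sqrt{1/nA + 1/nB})}
#' referred to a t distribution on d0 + d degrees of freedom. Shrinkage
#' borrows strength across probes, stabilising small-sample variance
#' estimates.
#'
#' The difference is reported as group B minus group A, so with beta
#' values as input \code{delta} is the methylation difference in beta
#' units (the "logFC" convention of array pipelines applied to beta
#' input). Setting \code{priorDf = 0} disables shrinkage and recovers the
#' ordinary pooled two-sample t exactly.
#'
#' Degenerate cases: if every probe has zero within-group variance the
#' statistic is undefined and the function falls back to exact-equality
#' calls (p = 0 where the group means differ, p = 1 where they are
#' equal), with a warning. If fewer than 50 probes have positive
#' variance, the moment fit is considered unreliable and shrinkage is
#' disabled with a warning.
#'
#' @param m numeric matrix, probes x samples (beta or M-values)
#' @param samplesA,samplesB column names or indices of the two groups
#'   (each >= 2 samples, no missing values)
#' @param priorDf NULL to fit the prior degrees of freedom from the data
#'   (default), or a nonnegative number (0 = no shrinkage) to fix it
#' @return data.frame with columns \code{probe_id}, \code{meanA},
#'   \code{meanB}, \code{delta} (B - A), \code{s2} (pooled), \code{s2Post}
#'   (shrunk), \code{t}, \code{df}, \code{p}, \code{padj} (BH); the fitted
#'   prior is attached as attributes \code{priorDf} and \code{priorVar}
#' @references Smyth (2004) Stat Appl Genet Mol Biol 3, Article 3
#' @export
moderatedT <- function(m, samplesA, samplesB, priorDf = NULL) {
    if (is(m, "MethylExperiment")) m <- getBeta(m)
    A <- m[, samplesA, drop = FALSE]
    B <- m[, samplesB, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    if (nA < 2 || nB < 2)
        stop("each group needs at least 2 samples (got ", nA, " and ",
             nB, ")")
    if (anyNA(A) || anyNA(B))
        stop("missing values in the selected columns")
    meanA <- rowMeans(A); meanB <- rowMeans(B)
    delta <- meanB - meanA
    d <- nA + nB - 2
    s2 <- ((nA - 1) * matrixStats::rowVars(A) +
           (nB - 1) * matrixStats::rowVars(B)) / d

    if (all(s2 == 0)) {
        warning("zero within-group variance everywhere; ",
                "falling back to exact-equality calls")
        p <- ifelse(delta == 0, 1, 0)
        res <- data.frame(probe_id = rownames(m), meanA = meanA,
                          meanB = meanB, delta = delta, s2 = s2,
                          s2Post = s2, t = ifelse(delta == 0, 0,
                                                  sign(delta) * Inf),
                          df = d, p = p, padj = bhAdjust(p),
                          row.names = NULL, stringsAsFactors = FALSE)
        attr(res, "priorDf") <- NA_real_
        attr(res, "priorVar") <- NA_real_
        return(res)
    }

    if (is.null(priorDf)) {
        pos <- s2 > 0
        if (sum(pos) < 50) {
            warning("fewer than 50 probes with positive variance; ",
                    "shrinkage disabled")
            d0 <- 0; s0 <- NA_real_
        } else {
            fit <- .fitVariancePrior(s2[pos], d)
            d0 <- fit$d0; s0 <- fit$s0
        }
    } else {
        stopifnot(priorDf >= 0)
        d0 <- priorDf
        s0 <- if (d0 > 0) mean(s2[s2 > 0]) else NA_real_
    }

    if (d0 == 0) {
        s2post <- s2
        dfTot <- d
    } else if (is.infinite(d0)) {
        s2post <- rep(s0, length(s2))
        dfTot <- Inf
    } else {
        s2post <- (d0 * s0 + d * s2) / (d0 + d)
        dfTot <- d0 + d
    }
    tt <- delta / sqrt(s2post * (1 / nA + 1 / nB))
    tt[delta == 0] <- 0
    p <- 2 * stats::pt(-abs(tt), df = dfTot)
    res <- data.frame(probe_id = rownames(m), meanA = meanA,
                      meanB = meanB, delta = delta, s2 = s2,
                      s2Post = s2post, t = tt, df = dfTot, p = p,
                      padj = bhAdjust(p), row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(res, "priorDf") <- d0
    attr(res, "priorVar") <- s0
    res
}

# Method-of-moments fit of the scaled-F prior on log variances:
# z = log(s2) has E[z] = log(s0) + digamma(d/2) - log(d/2)
#                       - digamma(d0/2) + log(d0/2)  ... (sign: see below)
# and Var[z] = trigamma(d/2) + trigamma(d0/2).
.fitVariancePrior <- function(s2, d) {
    z <- log(s2)
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- sum((e - emean)^2) / (n - 1)
    target <- evar - trigamma(d / 2)
    if (target > 0) {
        d0 <- 2 * .trigammaInverse(target)
        s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0 <- exp(emean)
    }
    list(d0 = d0, s0 = s0)
}

# Newton iteration for the inverse of the trigamma function.
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort p ascending, multiply p_(i) by m/i, enforce
#' monotonicity by a cumulative minimum from the largest p down, cap at
#' 1. Order-preserving: the ranking of adjusted values never crosses that
#' of the raw values.
#'
#' @param p numeric vector of p-values in [0,1]
#' @return adjusted p-values in the original order
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must be in [0,1] with no NA")
    m <- length(p)
    if (!m) return(numeric(0))
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))
    adj[order(o)]
}

#' Call differentially methylated probes at dual thresholds
#'
#' A probe is a DMP when its BH-adjusted p-value is below
#' \code{pAdjMax} and its absolute effect exceeds \code{absLfcMin}
#' (strict inequalities). The published convention is adjusted p < 0.01
#' and |logFC| > 0.3, which on the beta scale reads as a 30-percentage-
#' point methylation difference.
#'
#' @param stats data.frame from \code{\link{moderatedT}}
#' @param pAdjMax adjusted-p ceiling (default 0.01)
#' @param absLfcMin absolute effect floor (default 0.3)
#' @return the subset of \code{stats} rows passing both thresholds, with
#'   the thresholds attached as attribute \code{thresholds}
#' @export
callDMPs <- function(stats, pAdjMax = 0.01, absLfcMin = 0.3) {
    keep <- stats$padj < pAdjMax & abs(stats$delta) > absLfcMin
    out <- stats[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "thresholds") <- list(pAdjMax = pAdjMax,
                                    absLfcMin = absLfcMin)
    out
}

#' All-pairs differential methylation counting
#'
#' Applies \code{\link{moderatedT}} + \code{\link{callDMPs}} to every
#' unordered pair of sample groups and assembles the symmetric DMP count
#' matrix that feeds the relatedness network (23 groups evaluate 253
#' pairs). Groups with fewer than \code{minGroupSize} samples are skipped
#' with a warning. The BH adjustment is applied per pairwise comparison.
#'
#' @param m probe x sample matrix or a \linkS4class{MethylExperiment}
#' @param sheet sample sheet data.frame with \code{sample_id} and
#'   \code{group_label} (taken from the object if omitted)
#' @param pAdjMax,absLfcMin DMP thresholds (see \code{\link{callDMPs}})
#' @param scale \code{"beta"} (default; effects in beta units) or
#'   \code{"m"} (logit2-transform before testing)
#' @param minGroupSize smallest usable group (>= 2)
#' @return a \linkS4class{PairwiseDMP}
#' @export
pairwiseDMPCounts <- function(m, sheet = NULL, pAdjMax = 0.01,
                              absLfcMin = 0.3, scale = c("beta", "m"),
                              minGroupSize = 2) {
    scale <- match.arg(scale)
    if (is(m, "MethylExperiment")) {
        if (is.null(sheet)) sheet <- sampleSheet(m)
        m <- getBeta(m)
    }
    if (is.null(sheet)) stop("a sample sheet is required")
    stopifnot(minGroupSize >= 2)
    if (scale == "m") m <- betaToM(m)
    grp <- split(sheet$sample_id, sheet$group_label)
    grp <- grp[unique(sheet$group_label)]       # first-appearance order
    sizes <- lengths(grp)
    skipped <- names(grp)[sizes < minGroupSize]
    if (length(skipped))
        warning("groups skipped (< ", minGroupSize, " samples): ",
                paste(skipped, collapse = ", "))
    grp <- grp[sizes >= minGroupSize]
    G <- length(grp)
    if (G < 2) stop("need at least 2 usable groups")
    labels <- names(grp)
    counts <- matrix(0, G, G, dimnames = list(labels, labels))
    sets <- list()
    for (a in seq_len(G - 1)) for (b in seq(a + 1, G)) {
        st <- suppressWarnings(
            moderatedT(m, grp[[labels[a]]], grp[[labels[b]]]))
        dmps <- callDMPs(st, pAdjMax, absLfcMin)
        key <- paste(sort(c(labels[a], labels[b])), collapse = "|")
        sets[[key]] <- dmps
        counts[a, b] <- counts[b, a] <- nrow(dmps)
    }
    new("PairwiseDMP", counts = counts, sets = sets,
        thresholds = list(pAdjMax = pAdjMax, absLfcMin = absLfcMin),
        skipped = skipped)
}

#' Access pairwise DMP results
#'
#' @param object a \linkS4class{PairwiseDMP}
#' @return \code{dmpCounts}: the symmetric group x group count matrix;
#'   \code{dmpSet}: the DMP table for one unordered pair.
#' @export
setGeneric("dmpCounts", function(object) standardGeneric("dmpCounts"))

#' @rdname dmpCounts
#' @export
setMethod("dmpCounts", "PairwiseDMP", function(object) object@counts)

#' @rdname dmpCounts
#' @export
setGeneric("dmpSet", function(object, groupA, groupB)
    standardGeneric("dmpSet"))

#' @rdname dmpCounts
#' @param groupA,groupB group labels
#' @export
setMethod("dmpSet", "PairwiseDMP", function(object, groupA, groupB) {
    key <- paste(sort(c(groupA, groupB)), collapse = "|")
    if (is.null(object@sets[[key]]))
        stop("no DMP set for pair ", key)
    object@sets[[key]]
})

setMethod("show", "PairwiseDMP", function(object) {
    G <- nrow(object@counts)
    cat("PairwiseDMP:", G, "groups,", G * (G - 1) / 2,
        "pairs evaluated\n")
    cat("  thresholds: adj p <", object@thresholds$pAdjMax,
        ", |delta| >", object@thresholds$absLfcMin, "\n")
    cat("  DMP counts range:", min(object@counts[upper.tri(object@counts)]),
        "-", max(object@counts), "\n")
    if (length(object@skipped))
        cat("  skipped:", paste(object@skipped, collapse = ", "), "\n")
})
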