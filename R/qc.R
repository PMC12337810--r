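#' Sample-level quality control on detection p-values
#'
#' For each sample, computes the fraction of probes whose detection
#' p-value exceeds \code{pThreshold}; samples whose failing fraction
#' exceeds \code{maxFailFraction} are flagged for exclusion. The default
#' cap of 0.10 is a common array-QC convention (a sample failing at 14%
#' of probes is excluded under it).
#'
#' @param detP detection p-value matrix (probes x samples) or a
#'   \linkS4class{MethylExperiment} with a detP assay
#' @param pThreshold per-probe failure threshold (default 0.01)
#' @param maxFailFraction maximum tolerated failing fraction per sample
#' @return list of class \code{"QCReport"}: \code{failFraction} (named,
#'   per sample), \code{excluded} (sample ids), \code{pThreshold},
#'   \code{maxFailFraction}
#' @export
sampleQC <- function(detP, pThreshold = 0.01, maxFailFraction = 0.10) {
    if (is(detP, "MethylExperiment")) detP <- getDetP(detP)
    if (is.null(detP) || !nrow(detP) || !ncol(detP))
        stop("detection p matrix is empty")
    stopifnot(pThreshold > 0, pThreshold < 1,
              maxFailFraction > 0, maxFailFraction < 1)
    frac <- colMeans(detP > pThreshold, na.rm = TRUE)
    structure(list(failFraction = frac,
                   excluded = names(frac)[frac > maxFailFraction],
                   pThreshold = pThreshold,
                   maxFailFraction = maxFailFraction),
              class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
    cat("Sample QC: detection p >", x$pThreshold, "in more than",
        sprintf("%.0f%%", 100 * x$maxFailFraction), "of probes\n")
    cat(" ", length(x$failFraction), "samples,", length(x$excluded),
        "excluded")
    if (length(x$excluded))
        cat(":", paste(x$excluded, collapse = ", "))
    cat("\n")
    invisible(x)
}

#' Beta to M-value transform (and back)
#'
#' \code{m = log2(b / (1 - b))} with beta clipped to
#' \code{[epsilon, 1 - epsilon]} so the result is finite everywhere.
#' The M-value scale is the variance-stabilised scale conventional for
#' array statistics; the inverse maps M-values back to beta.
#'
#' @param beta numeric matrix or vector of beta values in [0,1]
#' @param epsilon clipping bound in (0, 0.1)
#' @return matrix/vector of the same shape
#' @examples
#' betaToM(0.5)   # 0
#' betaToM(0.8)   # 2
#' @export
betaToM <- function(beta, epsilon = 1e-3) {
    stopifnot(epsilon > 0, epsilon < 0.1)
    b <- pmin(pmax(beta, epsilon), 1 - epsilon)
    log2(b / (1 - b))
}

#' @rdname betaToM
#' @param m M-values
#' @export
mToBeta <- function(m) {
    2^m / (1 + 2^m)
}

#' Filter probes by annotation-based policies
#'
#' Supported policies: \code{"sex"} removes chrX/chrY probes;
#' \code{"missing"} removes probes with any NA beta value. Filters
#' commute (pure set intersection). Counts removed per filter are
#' reported via \code{message}.
#'
#' @param me a \linkS4class{MethylExperiment}
#' @param policy character vector of filter names (empty = identity)
#' @return the filtered \linkS4class{MethylExperiment}
#' @export
filterProbes <- function(me, policy = c("sex")) {
    stopifnot(is(me, "MethylExperiment"))
    if (!length(policy)) return(me)
    policy <- match.arg(policy, c("sex", "missing"), several.ok = TRUE)
    anno <- probeAnnotation(me)
    keep <- rep(TRUE, nrow(me))
    if ("sex" %in% policy) {
        if (!"chromosome" %in% names(anno))
            stop("annotation lacks a 'chromosome' column for the sex filter")
        sex <- anno$chromosome %in% c("chrX", "chrY", "X", "Y")
        message(sum(sex & keep), " sex-chromosome probes removed")
        keep <- keep & !sex
    }
    if ("missing" %in% policy) {
        hasNA <- rowSums(is.na(getBeta(me))) > 0
        message(sum(hasNA & keep), " probes with missing values removed")
        keep <- keep & !hasNA
    }
    me[keep, ]
}

#' Select the k most variable probes by standard deviation
#'
#' Ranks probes by across-sample standard deviation of their beta values
#' (descending) and returns the top \code{k}; the feature space used for
#' the heatmap / t-SNE / consensus landscape (typically k = 10,000).
#' Ties are broken lexicographically by probe id so the selection is
#' deterministic. If \code{k} exceeds the number of probes, all are
#' returned with a warning.
#'
#' @param m numeric matrix (probes x samples) or a
#'   \linkS4class{MethylExperiment}
#' @param k number of probes to keep
#' @return data.frame of class \code{"ProbeSubset"} with \code{probe_id}
#'   and \code{sd}, in selection order
#' @export
selectTopSD <- function(m, k) {
    if (is(m, "MethylExperiment")) m <- getBeta(m)
    stopifnot(k >= 1)
    sds <- matrixStats::rowSds(m, na.rm = TRUE)
    names(sds) <- rownames(m)
    if (k > nrow(m)) {
        warning("k = ", k, " exceeds ", nrow(m), " probes; returning all")
        k <- nrow(m)
    }
    ord <- order(-sds, rownames(m))
    sel <- ord[seq_len(k)]
    structure(data.frame(probe_id = rownames(m)[sel], sd = sds[sel],
                         row.names = NULL, stringsAsFactors = FALSE),
              class = c("ProbeSubset", "data.frame"))
}
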