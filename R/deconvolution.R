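#' Promoter-methylation-derived gene activity
#'
#' Simple monotone surrogate for expression from promoter methylation:
#' \code{activity(gene, sample) = 1 - mean(beta over the gene's TSS
#' probes)}. Fully methylated promoters score 0, unmethylated promoters
#' 1. Genes without any TSS probe are omitted with a message. The
#' transform is pluggable via \code{transform}.
#'
#' @param beta probe x sample beta matrix or
#'   \linkS4class{MethylExperiment}
#' @param annotation probe annotation with \code{probe_id},
#'   \code{gene_symbol}, \code{tss_flag} (taken from the object if
#'   omitted)
#' @param transform function applied to the per-gene mean TSS beta
#'   (default \code{function(b) 1 - b})
#' @return gene x sample activity matrix in [0,1] for the default
#'   transform
#' @export
geneActivityFromBeta <- function(beta, annotation = NULL,
                                 transform = function(b) 1 - b) {
    if (is(beta, "MethylExperiment")) {
        if (is.null(annotation)) annotation <- probeAnnotation(beta)
        beta <- getBeta(beta)
    }
    if (is.null(annotation)) stop("probe annotation is required")
    ann <- annotation[match(rownames(beta), annotation$probe_id), ]
    keep <- which(ann$tss_flag & !is.na(ann$gene_symbol) &
                  nzchar(ann$gene_symbol))
    if (!length(keep)) stop("no TSS probes with gene symbols")
    nGenesAll <- length(unique(ann$gene_symbol[
        !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)]))
    g <- factor(ann$gene_symbol[keep])
    sums <- rowsum(beta[keep, , drop = FALSE], g)
    act <- transform(sums / as.vector(table(g)))
    omitted <- nGenesAll - nlevels(g)
    if (omitted > 0)
        message(omitted, " genes without TSS probes omitted")
    act
}

#' Estimate cell-type fractions by constrained least squares
#'
#' Per sample, solves \deqn{\min_f \|S f - a\|^2 \quad s.t.\ f \ge 0,\
#' \sum f = 1} where S is the cell-type signature over the features
#' shared (by id) between activity and signature. The solver is
#' nonnegative least squares on a system augmented with a heavily
#' weighted sum-to-one row, renormalised onto the simplex; an exact
#' equality-constrained active-set solver is used as an internal
#' cross-check and both agree to 1e-6 on well-posed problems. The
#' sum-to-one constraint makes the fractions invariant to a common
#' positive rescaling of activity and signature.
#'
#' @param activity features x samples matrix
#'   (\code{\link{geneActivityFromBeta}} output or any nonnegative
#'   scores)
#' @param signature features x cell types reference matrix
#' @return list of class \code{"FractionEstimate"}: \code{fractions}
#'   (samples x cell types, rows on the simplex), \code{residual}
#'   (per-sample residual norm), \code{nFeatures} (shared features used)
#' @export
estimateFractions <- function(activity, signature) {
    shared <- intersect(rownames(activity), rownames(signature))
    if (length(shared) < ncol(signature))
        stop("only ", length(shared), " shared features for ",
             ncol(signature), " cell types")
    S <- signature[shared, , drop = FALSE]
    A <- activity[shared, , drop = FALSE]
    if (any(rowSums(S != 0) == 0)) stop("signature has all-zero rows")
    lambda <- 1e4 * max(abs(S))
    Saug <- rbind(S, lambda)
    K <- ncol(S)
    frac <- matrix(NA_real_, ncol(A), K,
                   dimnames = list(colnames(A), colnames(S)))
    resid <- numeric(ncol(A))
    for (j in seq_len(ncol(A))) {
        f <- pracma::lsqnonneg(Saug, c(A[, j], lambda))$x
        f <- pmax(f, 0)
        f <- f / sum(f)                 # project onto the simplex
        frac[j, ] <- f
        resid[j] <- sqrt(sum((S %*% f - A[, j])^2))
    }
    structure(list(fractions = frac, residual = resid,
                   nFeatures = length(shared)),
              class = "FractionEstimate")
}

# Exact equality-constrained NNLS by active set on the KKT system:
# minimise ||Sf - a||^2 s.t. 1'f = 1, f_i = 0 for i in the active set.
# Used as an internal cross-check of the augmented-system solver.
.fractionsActiveSet <- function(S, a, tol = 1e-10, maxIter = 100) {
    K <- ncol(S)
    free <- rep(TRUE, K)
    for (it in seq_len(maxIter)) {
        idx <- which(free)
        Sf <- S[, idx, drop = FALSE]
        # KKT: [S'S  1; 1' 0] [f; mu] = [S'a; 1] on the free coordinates
        kkt <- rbind(cbind(crossprod(Sf), 1), c(rep(1, length(idx)), 0))
        rhs <- c(crossprod(Sf, a), 1)
        sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
        if (is.null(sol)) {
            sol <- c(MASS_ginv(kkt) %*% rhs)
        }
        f <- sol[seq_along(idx)]
        if (all(f >= -tol)) {
            out <- numeric(K)
            out[idx] <- pmax(f, 0)
            return(out / sum(out))
        }
        free[idx[which.min(f)]] <- FALSE
        if (sum(free) == 1) {
            out <- numeric(K)
            out[free] <- 1
            return(out)
        }
    }
    stop("active-set solver failed to converge")
}

# minimal Moore-Penrose pseudoinverse (avoids a MASS dependency for one
# degenerate-KKT corner case)
MASS_ginv <- function(X, tol = 1e-10) {
    s <- svd(X)
    pos <- s$d > tol * s$d[1]
    s$v[, pos, drop = FALSE] %*%
        (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.FractionEstimate <- function(x, ...) {
    cat("FractionEstimate:", nrow(x$fractions), "samples x",
        ncol(x$fractions), "cell types (", x$nFeatures, "features )\n")
    cat("  mean residual norm:", signif(mean(x$residual), 4), "\n")
    invisible(x)
}

#' Compare estimated cell-type fractions between two groups
#'
#' Per cell type, tests the fraction distributions of two sample groups
#' following the normality-gated rule: Shapiro-Wilk on each group at
#' alpha = 0.05; if both pass, a two-sided unpaired (pooled-variance)
#' t-test, otherwise the Mann-Whitney test. P-values are mapped to the
#' conventional star categories (ns, * p<0.05, ** p<0.01, *** p<0.001,
#' **** p<0.0001). Groups with constant values (Shapiro undefined) fall
#' to Mann-Whitney.
#'
#' @param fractions a \code{"FractionEstimate"} or samples x cell types
#'   matrix
#' @param sheet sample sheet with \code{sample_id}, \code{group_label}
#' @param groupA,groupB group labels (each >= 3 samples)
#' @return data.frame: \code{cellType}, \code{test} ("t" or
#'   "mann-whitney"), \code{statistic}, \code{p}, \code{stars}
#' @export
compareFractions <- function(fractions, sheet, groupA, groupB) {
    fm <- if (inherits(fractions, "FractionEstimate"))
        fractions$fractions else fractions
    for (g in c(groupA, groupB))
        if (!g %in% sheet$group_label) stop("group not found: ", g)
    idsA <- intersect(sheet$sample_id[sheet$group_label == groupA],
                      rownames(fm))
    idsB <- intersect(sheet$sample_id[sheet$group_label == groupB],
                      rownames(fm))
    if (length(idsA) < 3 || length(idsB) < 3)
        stop("both groups need at least 3 samples with fractions")
    rows <- lapply(colnames(fm), function(ct) {
        a <- fm[idsA, ct]; b <- fm[idsB, ct]
        normA <- .isNormal(a); normB <- .isNormal(b)
        if (normA && normB) {
            tt <- stats::t.test(a, b, var.equal = TRUE)
            data.frame(cellType = ct, test = "t",
                       statistic = unname(tt$statistic), p = tt$p.value,
                       stringsAsFactors = FALSE)
        } else {
            wt <- suppressWarnings(
                stats::wilcox.test(a, b, exact = FALSE))
            pv <- if (is.na(wt$p.value)) 1 else wt$p.value
            data.frame(cellType = ct, test = "mann-whitney",
                       statistic = unname(wt$statistic), p = pv,
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$stars <- starCategory(out$p)
    out
}

.isNormal <- function(x, alpha = 0.05) {
    if (length(unique(x)) < 3) return(FALSE)
    sw <- tryCatch(stats::shapiro.test(x), error = function(e) NULL)
    !is.null(sw) && sw$p.value >= alpha
}

#' Star category for a p-value
#'
#' \code{ns}, \code{*} p<0.05, \code{**} p<0.01, \code{***} p<0.001,
#' \code{****} p<0.0001.
#' @param p numeric vector of p-values
#' @return character vector of star labels
#' @export
starCategory <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "ns"),
        right = FALSE) |> as.character()
}
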