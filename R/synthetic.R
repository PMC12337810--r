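#' Configuration for the synthetic EPIC-like cohort generator
#'
#' Describes a cohort with a planted group structure: per-probe baseline
#' methylation drawn from a bimodal beta distribution, group-specific
#' methylation shifts ("planted DMPs") applied on selected probes,
#' logit-scale Gaussian noise, and designated QC-failing samples whose
#' detection p-values exceed 0.01 at a configured fraction of probes.
#'
#' Planting is additive and per-pair: an entry \code{list(pair = c("A","B"),
#' n = 400, delta = 0.35)} shifts the mean of group B (only) by
#' \code{delta} beta units on \code{n} previously unplanted probes, in the
#' direction that keeps the shifted mean inside [0.01, 0.99]. An entry may
#' instead carry \code{sameAs = j} to reuse the probes and shift of entry
#' \code{j}, which makes two groups exact distributional siblings with
#' respect to those probes (zero true DMPs between them).
#'
#' @param nProbes number of array probes
#' @param groups named integer vector: group label -> number of samples
#' @param plantedDMPs list of planting entries (see Details)
#' @param baseModes list with \code{low} and \code{high} Beta shape pairs
#'   for the bimodal baseline (defaults Beta(2,18) and Beta(18,2), mixed
#'   50/50 per probe)
#' @param noiseSd standard deviation of per-sample noise on the logit
#'   scale
#' @param badSamples named numeric vector: sample id -> fraction of probes
#'   with failing detection p (> 0.01)
#' @param seed integer RNG seed
#' @return a validated list of class \code{"SyntheticConfig"}
#' @seealso \code{\link{generateCohort}}, \code{\link{defaultSyntheticConfig}}
#' @export
syntheticConfig <- function(nProbes, groups, plantedDMPs = list(),
                            baseModes = list(low = c(2, 18),
                                             high = c(18, 2)),
                            noiseSd = 0.1, badSamples = numeric(0),
                            seed = 1) {
    stopifnot(nProbes >= 1, length(groups) >= 1, noiseSd >= 0)
    if (is.null(names(groups)) || anyDuplicated(names(groups)))
        stop("group labels must be unique and named")
    if (any(groups < 1)) stop("each group needs at least one sample")
    for (i in seq_along(plantedDMPs)) {
        e <- plantedDMPs[[i]]
        if (is.null(e$pair) || length(e$pair) != 2 ||
            !all(e$pair %in% names(groups)))
            stop("plantedDMPs[[", i, "]]: 'pair' must name two known groups")
        if (is.null(e$sameAs)) {
            if (is.null(e$n) || e$n < 1)
                stop("plantedDMPs[[", i, "]]: 'n' must be >= 1")
            if (is.null(e$delta) || e$delta <= 0 || e$delta > 0.98)
                stop("plantedDMPs[[", i,
                     "]]: 'delta' must be in (0, 0.98] to keep shifted ",
                     "means inside [0.01, 0.99]")
        } else if (e$sameAs >= i || e$sameAs < 1) {
            stop("plantedDMPs[[", i, "]]: 'sameAs' must point to an ",
                 "earlier entry")
        }
    }
    if (length(badSamples) && (is.null(names(badSamples)) ||
        any(badSamples < 0 | badSamples > 1)))
        stop("badSamples must be a named vector of fractions in [0,1]")
    structure(list(nProbes = as.integer(nProbes), groups = groups,
                   plantedDMPs = plantedDMPs, baseModes = baseModes,
                   noiseSd = noiseSd, badSamples = badSamples,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

#' Default synthetic cohort: six entities, planted sibling pair
#'
#' 20,000 probes x 150 samples across six groups modelled on a
#' pancreato-ovarian landscape: a normal-tissue baseline and five lesion
#' groups each shifted on its own probe set, with MCN_P and MCN_L planted
#' as exact siblings (identical shift sets, hence zero true DMPs between
#' them) and one designated QC-failing sample at a 14% detection-p failure
#' fraction.
#'
#' @param seed integer RNG seed
#' @param nProbes,noiseSd override the default scale / noise; planted
#'   probe counts scale proportionally with \code{nProbes} so the
#'   planting density is preserved
#' @return a \code{"SyntheticConfig"}
#' @export
defaultSyntheticConfig <- function(seed = 1, nProbes = 20000,
                                   noiseSd = 0.1) {
    f <- nProbes / 20000
    syntheticConfig(
        nProbes = nProbes,
        groups = c(MCN_P = 20, MCN_L = 15, mBOT = 25, PMOC = 25,
                   PDAC = 35, NormPancreas = 30),
        plantedDMPs = list(
            list(pair = c("NormPancreas", "PDAC"),
                 n = round(3000 * f), delta = 0.35),
            list(pair = c("NormPancreas", "mBOT"),
                 n = round(2500 * f), delta = 0.35),
            list(pair = c("NormPancreas", "PMOC"),
                 n = round(2600 * f), delta = 0.35),
            list(pair = c("NormPancreas", "MCN_P"),
                 n = round(2000 * f), delta = 0.35),
            list(pair = c("NormPancreas", "MCN_L"), sameAs = 4)),
        noiseSd = noiseSd,
        badSamples = c(MCN_P_01 = 0.14),
        seed = seed)
}

#' Generate a synthetic EPIC-like cohort with planted ground truth
#'
#' Draws per-probe baseline means from the configured bimodal beta
#' mixture, applies the planted group shifts, realises per-sample beta
#' values by adding Gaussian noise on the logit scale and mapping back to
#' [0,1], and builds companion detection p-values, sample sheet and probe
#' annotation. The returned ground truth lists, for every group pair, the
#' probes whose true group means differ (the planted DMPs).
#'
#' @param config a \code{"SyntheticConfig"} from \code{\link{syntheticConfig}}
#' @return list with \code{experiment} (a \linkS4class{MethylExperiment})
#'   and \code{groundTruth} (list: \code{dmpProbesPerPair} named
#'   "A|B" -> probe ids with labels sorted within each pair,
#'   \code{clusterAssignment} sample -> group label,
#'   \code{siblingGroups} groups sharing identical shift sets)
#' @examples
#' cfg <- syntheticConfig(500, c(A = 5, B = 5), list(
#'     list(pair = c("A", "B"), n = 40, delta = 0.35)), seed = 7)
#' cohort <- generateCohort(cfg)
#' length(cohort$groundTruth$dmpProbesPerPair[["A|B"]])  # 40
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed)
    nP <- config$nProbes
    labels <- names(config$groups)
    probeIds <- sprintf("cg%07d", seq_len(nP))

    lo <- config$baseModes$low
    hi <- config$baseModes$high
    isHigh <- stats::runif(nP) < 0.5
    base <- ifelse(isHigh, stats::rbeta(nP, hi[1], hi[2]),
                           stats::rbeta(nP, lo[1], lo[2]))
    base <- pmin(pmax(base, 0.01), 0.99)

    # resolve planting: signed per-group shifts, additive across entries
    shift <- matrix(0, nP, length(labels), dimnames = list(NULL, labels))
    pool <- seq_len(nP)            # probes not yet planted
    resolved <- vector("list", length(config$plantedDMPs))
    for (i in seq_along(config$plantedDMPs)) {
        e <- config$plantedDMPs[[i]]
        if (!is.null(e$sameAs)) {
            src <- resolved[[e$sameAs]]
            idx <- src$idx; signed <- src$signed
        } else {
            if (e$n > length(pool))
                stop("not enough unplanted probes for entry ", i)
            idx <- sort(sample(pool, e$n))
            pool <- setdiff(pool, idx)
            up <- base[idx] + e$delta <= 0.99
            signed <- ifelse(up, e$delta, -e$delta)
            if (any(base[idx] + signed < 0.01 | base[idx] + signed > 0.99))
                stop("delta pushes a shifted mean outside [0.01, 0.99]")
        }
        resolved[[i]] <- list(idx = idx, signed = signed)
        shift[idx, e$pair[2]] <- shift[idx, e$pair[2]] + signed
    }
    mu <- base + shift
    if (any(mu < 0.005 | mu > 0.995))
        stop("additive planting pushed a group mean outside (0,1)")

    sampleIds <- unlist(lapply(labels, function(g)
        sprintf("%s_%02d", g, seq_len(config$groups[[g]]))))
    groupOf <- rep(labels, times = config$groups)

    beta <- matrix(NA_real_, nP, length(sampleIds),
                   dimnames = list(probeIds, sampleIds))
    for (j in seq_along(sampleIds)) {
        m <- mu[, groupOf[j]]
        beta[, j] <- if (config$noiseSd == 0) m else
            stats::plogis(stats::qlogis(m) +
                          stats::rnorm(nP, 0, config$noiseSd))
    }

    detP <- matrix(stats::runif(nP * length(sampleIds), 0, 0.009),
                   nP, length(sampleIds),
                   dimnames = list(probeIds, sampleIds))
    for (s in names(config$badSamples)) {
        if (!s %in% sampleIds)
            stop("badSamples names an unknown sample: ", s)
        nFail <- round(config$badSamples[[s]] * nP)
        fail <- sample.int(nP, nFail)
        detP[fail, s] <- stats::runif(nFail, 0.02, 0.8)
    }

    sheet <- data.frame(sample_id = sampleIds, group_label = groupOf,
                        material = "FFPE", grade = NA_character_,
                        mutation_status = NA_character_,
                        stringsAsFactors = FALSE)

    nGenes <- ceiling(nP / 3)
    anno <- data.frame(
        probe_id = probeIds,
        chromosome = sample(c(paste0("chr", 1:22), "chrX", "chrY"), nP,
                            replace = TRUE,
                            prob = c(rep(0.98 / 22, 22), 0.015, 0.005)),
        position = sample.int(2e8, nP, replace = TRUE),
        gene_symbol = rep(sprintf("GENE%05d", seq_len(nGenes)),
                          each = 3)[seq_len(nP)],
        tss_flag = stats::runif(nP) < 0.3,
        stringsAsFactors = FALSE)

    # ground truth: probes whose true means differ, per unordered pair
    dmp <- list()
    if (length(labels) > 1) {
        for (a in seq_len(length(labels) - 1))
            for (b in seq(a + 1, length(labels))) {
                d <- which(mu[, labels[a]] != mu[, labels[b]])
                key <- paste(sort(c(labels[a], labels[b])), collapse = "|")
                dmp[[key]] <- probeIds[d]
            }
    }
    sib <- names(which(vapply(dmp, length, 0L) == 0))

    me <- MethylExperiment(beta, detP = detP, sampleSheet = sheet,
                           probeAnnotation = anno)
    list(experiment = me,
         groundTruth = list(
             dmpProbesPerPair = dmp,
             clusterAssignment = stats::setNames(groupOf, sampleIds),
             siblingGroups = sib,
             groupMeans = mu))
}

#' Generate a block-dominant cell-type signature matrix
#'
#' Each cell type receives \code{nMarkersPerType} marker features on which
#' its reference value is at least three times that of every other type,
#' yielding a well-conditioned signature for deconvolution tests.
#'
#' @param nCellTypes number of cell types (>= 2)
#' @param nMarkersPerType markers per type (>= 1)
#' @param seed integer RNG seed
#' @return numeric matrix, (nCellTypes * nMarkersPerType) features x
#'   nCellTypes, with marker and cell-type names
#' @export
generateReferenceSignature <- function(nCellTypes, nMarkersPerType,
                                       seed = 1) {
    if (nCellTypes < 2) stop("need at least 2 cell types")
    stopifnot(nMarkersPerType >= 1)
    set.seed(seed)
    nF <- nCellTypes * nMarkersPerType
    sig <- matrix(0, nF, nCellTypes,
                  dimnames = list(sprintf("M%04d", seq_len(nF)),
                                  sprintf("CellType%d", seq_len(nCellTypes))))
    for (t in seq_len(nCellTypes)) {
        rows <- (t - 1) * nMarkersPerType + seq_len(nMarkersPerType)
        own <- stats::runif(nMarkersPerType, 6, 10)
        sig[rows, t] <- own
        for (o in setdiff(seq_len(nCellTypes), t))
            sig[rows, o] <- stats::runif(nMarkersPerType, 0.1, own / 3.05)
    }
    sig
}

#' Generate noisy mixtures of signature columns
#'
#' \code{activity = signature \%*\% t(fractions) + noise}, truncated at
#' zero so activities stay nonnegative.
#'
#' @param signature features x cell types matrix
#' @param fractions samples x cell types matrix; rows nonnegative, each
#'   summing to 1
#' @param noiseSd standard deviation of additive Gaussian noise
#' @param seed integer RNG seed
#' @return features x samples activity matrix
#' @export
generateMixtures <- function(signature, fractions, noiseSd = 0, seed = 1) {
    fractions <- as.matrix(fractions)
    if (any(fractions < 0)) stop("fractions must be nonnegative")
    if (any(abs(rowSums(fractions) - 1) > 1e-9))
        stop("fraction rows must sum to 1")
    if (ncol(fractions) != ncol(signature))
        stop("fractions columns must match signature cell types")
    set.seed(seed)
    act <- signature %*% t(fractions)
    if (noiseSd > 0)
        act <- act + stats::rnorm(length(act), 0, noiseSd)
    act <- pmax(act, 0)
    if (is.null(rownames(fractions)))
        rownames(fractions) <- sprintf("S%03d", seq_len(nrow(fractions)))
    colnames(act) <- rownames(fractions)
    act
}
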