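# Small fixture builders shared across the suite. Everything is
# generated in code; no stored binary data.

# three well-separated groups, one planted pair; small enough for fast
# unit tests
smallCohort <- function(seed = 3, noiseSd = 0.1, nProbes = 2000,
                        n = 10, delta = 0.35, nPlanted = 150) {
    cfg <- syntheticConfig(
        nProbes, c(A = n, B = n, C = n),
        plantedDMPs = list(
            list(pair = c("A", "B"), n = nPlanted, delta = delta),
            list(pair = c("A", "C"), n = nPlanted, delta = delta)),
        noiseSd = noiseSd, seed = seed)
    generateCohort(cfg)
}

groupSamples <- function(me, g) {
    sheet <- sampleSheet(me)
    sheet$sample_id[sheet$group_label == g]
}

# adjusted Rand index, direct pair-counting form
ari <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}

# ordinary pooled two-sample t, the no-shrinkage oracle
pooledT <- function(m, A, B) {
    a <- m[, A, drop = FALSE]; b <- m[, B, drop = FALSE]
    nA <- ncol(a); nB <- ncol(b)
    s2 <- ((nA - 1) * apply(a, 1, var) + (nB - 1) * apply(b, 1, var)) /
        (nA + nB - 2)
    tt <- (rowMeans(b) - rowMeans(a)) / sqrt(s2 * (1 / nA + 1 / nB))
    list(t = tt, p = 2 * pt(-abs(tt), nA + nB - 2))
}

writeTempGMT <- function(lines) {
    f <- tempfile(fileext = ".gmt")
    writeLines(lines, f)
    f
}
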