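test_that("promoter activity is 1 minus the mean TSS beta", {
    b <- rbind(p1 = c(0, 1), p2 = c(0.2, 1), p3 = c(0.4, 1),
               p4 = c(0.9, 0.1))
    colnames(b) <- c("s1", "s2")
    anno <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       chromosome = "chr1", position = 1:4,
                       gene_symbol = c("G1", "G2", "G2", "G3"),
                       tss_flag = c(TRUE, TRUE, TRUE, FALSE))
    act <- suppressMessages(geneActivityFromBeta(b, anno))
    expect_equal(act["G1", "s1"], 1)      # beta 0 -> fully active
    expect_equal(act["G1", "s2"], 0)      # fully methylated -> 0
    expect_equal(act["G2", "s1"], 1 - mean(c(0.2, 0.4)))  # 0.7
    # G3 has no TSS probe: omitted
    expect_false("G3" %in% rownames(act))
    expect_message(geneActivityFromBeta(b, anno), "1 genes without")
})

test_that("a pure sample recovers fraction 1 for its type", {
    sig <- generateReferenceSignature(4, 20, seed = 3)
    act <- sig[, 2, drop = FALSE]
    colnames(act) <- "pure"
    fe <- estimateFractions(act, sig)
    expect_equal(unname(fe$fractions["pure", ]),
                 c(0, 1, 0, 0), tolerance = 1e-6)
    expect_lt(fe$residual, 1e-6)
})

test_that("Dirichlet mixtures at 5% noise are recovered with low error and bias", {
    sig <- generateReferenceSignature(4, 25, seed = 1)
    set.seed(9)
    fr <- matrix(rgamma(50 * 4, 1), 50)
    fr <- fr / rowSums(fr)
    rownames(fr) <- sprintf("S%03d", 1:50)
    act <- generateMixtures(sig, fr, noiseSd = 0.05 * sd(sig), seed = 2)
    fe <- estimateFractions(act, sig)
    expect_lt(sqrt(mean((fe$fractions - fr)^2)), 0.05)
    expect_lt(max(abs(colMeans(fe$fractions - fr))), 0.01)
    expect_true(all(abs(rowSums(fe$fractions) - 1) < 1e-6))
    expect_true(all(fe$fractions >= 0))
})

test_that("the solver equals a 0.01-step grid search on 2-type problems", {
    sig <- generateReferenceSignature(2, 10, seed = 5)
    set.seed(4)
    for (trueF in c(0.0, 0.23, 0.5, 0.87, 1.0)) {
        a <- sig %*% c(trueF, 1 - trueF) + rnorm(nrow(sig), 0, 0.1)
        a <- pmax(a, 0)
        colnames(a) <- "mix"
        fe <- estimateFractions(a, sig)
        grid <- seq(0, 1, by = 0.01)
        sse <- vapply(grid, function(f)
            sum((sig %*% c(f, 1 - f) - a)^2), 0)
        best <- grid[which.min(sse)]
        expect_lt(abs(fe$fractions[1, 1] - best), 0.01 + 1e-9)
    }
})

test_that("augmented-NNLS and exact active-set solvers agree to 1e-6", {
    sig <- generateReferenceSignature(5, 15, seed = 7)
    set.seed(11)
    fr <- matrix(rgamma(20 * 5, 1), 20)
    fr <- fr / rowSums(fr)
    rownames(fr) <- sprintf("S%03d", 1:20)
    act <- generateMixtures(sig, fr, noiseSd = 0.1, seed = 3)
    fe <- estimateFractions(act, sig)
    for (j in seq_len(ncol(act))) {
        exact <- MethylScape:::.fractionsActiveSet(sig, act[, j])
        expect_equal(unname(fe$fractions[j, ]), exact,
                     tolerance = 1e-6)
    }
})

test_that("fractions are invariant to a common positive rescaling", {
    sig <- generateReferenceSignature(3, 12, seed = 9)
    set.seed(5)
    fr <- matrix(c(0.2, 0.5, 0.3), 1)
    rownames(fr) <- "s1"
    act <- generateMixtures(sig, fr, noiseSd = 0.05, seed = 6)
    f1 <- estimateFractions(act, sig)$fractions
    f2 <- estimateFractions(act * 7.3, sig * 7.3)$fractions
    expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("the solver is deterministic across repeated runs", {
    sig <- generateReferenceSignature(4, 10, seed = 2)
    set.seed(8)
    fr <- matrix(rgamma(10 * 4, 1), 10)
    fr <- fr / rowSums(fr)
    rownames(fr) <- sprintf("S%02d", 1:10)
    act <- generateMixtures(sig, fr, noiseSd = 0.2, seed = 4)
    expect_identical(estimateFractions(act, sig)$fractions,
                     estimateFractions(act, sig)$fractions)
})

test_that("feature intersection smaller than the number of types is rejected", {
    sig <- generateReferenceSignature(4, 5, seed = 1)
    act <- matrix(1, 2, 3, dimnames = list(rownames(sig)[1:2],
                                           paste0("s", 1:3)))
    expect_error(estimateFractions(act, sig), "shared features")
})

test_that("identical groups are non-significant; planted shifts reach ****", {
    set.seed(12)
    nms <- sprintf("s%02d", 1:40)
    sheet <- data.frame(sample_id = nms,
                        group_label = rep(c("A", "B"), each = 20))
    # identical distributions
    f0 <- cbind(t1 = rnorm(40, 0.5, 0.02), t2 = rnorm(40, 0.5, 0.02))
    f0 <- f0 / rowSums(f0)
    rownames(f0) <- nms
    tab0 <- compareFractions(f0, sheet, "A", "B")
    expect_true(all(tab0$stars == "ns"))
    # planted 0.3 shift at n = 20/20, noise 0.02
    f1 <- cbind(t1 = c(rnorm(20, 0.2, 0.02), rnorm(20, 0.5, 0.02)))
    f1 <- cbind(f1, t2 = 1 - f1[, 1])
    rownames(f1) <- nms
    tab1 <- compareFractions(f1, sheet, "A", "B")
    expect_true(all(tab1$stars == "****"))
})

test_that("the Shapiro-Wilk gate routes to Mann-Whitney for non-normal data", {
    set.seed(21)
    nms <- sprintf("s%02d", 1:40)
    sheet <- data.frame(sample_id = nms,
                        group_label = rep(c("A", "B"), each = 20))
    # heavily skewed fractions: lognormal-ish
    raw <- exp(rnorm(40, -2, 1.5))
    f <- cbind(t1 = raw, t2 = 1 - raw)
    f[f < 0] <- 0; f <- f / rowSums(f)
    rownames(f) <- nms
    tab <- compareFractions(f, sheet, "A", "B")
    expect_true("mann-whitney" %in% tab$test)
    # normal data routes to the t-test
    g <- cbind(t1 = rnorm(40, 0.5, 0.05))
    g <- cbind(g, t2 = 1 - g[, 1])
    rownames(g) <- nms
    tab2 <- compareFractions(g, sheet, "A", "B")
    expect_true(all(tab2$test == "t"))
})

test_that("star categories match the published thresholds", {
    expect_identical(starCategory(c(0.3, 0.05, 0.03, 0.004, 3e-4, 5e-5)),
                     c("ns", "ns", "*", "**", "***", "****"))
})
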