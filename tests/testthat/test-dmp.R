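test_that("identical group means give t = 0 and two-sided p = 1", {
    set.seed(2)
    noise <- rnorm(4, 0, 0.01)
    m <- rbind(cg1 = 0.5 + c(noise, noise),
               cg2 = runif(8))
    colnames(m) <- paste0("s", 1:8)
    st <- suppressWarnings(moderatedT(m, paste0("s", 1:4),
                                      paste0("s", 5:8)))
    expect_equal(st$delta[1], 0)
    expect_equal(st$t[1], 0)
    expect_equal(st$p[1], 1)
})

test_that("disabling shrinkage reproduces the pooled two-sample t within 1e-10", {
    set.seed(4)
    for (rep in 1:3) {
        m <- matrix(runif(200 * 12), 200, 12,
                    dimnames = list(sprintf("cg%03d", 1:200),
                                    paste0("s", 1:12)))
        A <- paste0("s", 1:6); B <- paste0("s", 7:12)
        st <- moderatedT(m, A, B, priorDf = 0)
        oracle <- pooledT(m, A, B)
        expect_equal(st$t, unname(oracle$t), tolerance = 1e-10)
        expect_equal(st$p, unname(oracle$p), tolerance = 1e-10)
        expect_true(all(st$df == 10))
    }
})

test_that("a single-probe matrix degenerates to the ordinary t", {
    set.seed(9)
    m <- matrix(runif(10), 1, 10,
                dimnames = list("cg1", paste0("s", 1:10)))
    A <- paste0("s", 1:5); B <- paste0("s", 6:10)
    st <- suppressWarnings(moderatedT(m, A, B))   # < 50 probes: no shrink
    oracle <- pooledT(m, A, B)
    expect_equal(st$t, unname(oracle$t), tolerance = 1e-12)
})

test_that("the fitted empirical-Bayes prior matches the reference implementation", {
    skip_if_not_installed("limma")
    co <- smallCohort(seed = 3, nProbes = 1500)
    me <- co$experiment
    A <- groupSamples(me, "A"); B <- groupSamples(me, "B")
    st <- moderatedT(getBeta(me), A, B)
    design <- cbind(1, c(rep(0, length(A)), rep(1, length(B))))
    fit <- limma::eBayes(limma::lmFit(getBeta(me)[, c(A, B)], design))
    expect_equal(attr(st, "priorDf"), fit$df.prior, tolerance = 1e-8)
    expect_equal(attr(st, "priorVar"), fit$s2.prior, tolerance = 1e-8)
    expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-9)
    expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-9)
})

test_that("all-zero within-group variance falls back to exact-equality calls", {
    # cg1: 0.2 vs 0.8 (group means differ); cg2: constant everywhere
    m <- rbind(cg1 = rep(c(0.2, 0.8), each = 4), cg2 = rep(0.6, 8))
    colnames(m) <- paste0("s", 1:8)
    expect_warning(st <- moderatedT(m, paste0("s", 1:4),
                                    paste0("s", 5:8)),
                   "exact-equality")
    expect_equal(st$p, c(0, 1))
})

test_that("swapping groups flips delta and preserves |t|, p and the call set", {
    co <- smallCohort(seed = 17, nProbes = 800)
    b <- getBeta(co$experiment)
    A <- groupSamples(co$experiment, "A")
    B <- groupSamples(co$experiment, "B")
    ab <- moderatedT(b, A, B)
    ba <- moderatedT(b, B, A)
    expect_equal(ab$delta, -ba$delta)
    expect_equal(abs(ab$t), abs(ba$t))
    expect_equal(ab$p, ba$p)
    expect_setequal(callDMPs(ab)$probe_id, callDMPs(ba)$probe_id)
})

test_that("BH step-up matches hand computation and brute force on small cases", {
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "0,1")

    # brute-force step-up oracle on all permutations of <= 6 p-values
    bruteBH <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- numeric(m)
        running <- 1
        for (i in m:1) {
            running <- min(running, p[o[i]] * m / i)
            adj[o[i]] <- running
        }
        adj
    }
    base <- c(0.001, 0.009, 0.041, 0.049, 0.3, 0.9)
    set.seed(1)
    for (i in 1:20) {
        p <- sample(base)
        expect_equal(bhAdjust(p), bruteBH(p))
        expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    }
    # ties and duplicates
    p <- c(0.05, 0.05, 0.01, 0.8)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
})

test_that("BH adjustment is order-preserving and >= raw p", {
    set.seed(7)
    p <- runif(500)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("the dual-threshold DMP call respects strict boundaries", {
    st <- data.frame(probe_id = c("a", "b", "c", "d"),
                     delta = c(0.35, 0.29, 0.31, -0.35),
                     padj = c(0.005, 0.005, 0.01, 0.002))
    out <- callDMPs(st)
    expect_setequal(out$probe_id, c("a", "d"))   # b fails |d|, c fails p
    thr <- attr(out, "thresholds")
    expect_equal(thr$pAdjMax, 0.01)
    expect_equal(thr$absLfcMin, 0.3)
})

test_that("tightening either threshold yields a subset of the call set", {
    set.seed(3)
    st <- data.frame(probe_id = sprintf("p%03d", 1:300),
                     delta = rnorm(300, 0, 0.3),
                     padj = runif(300))
    base <- callDMPs(st, 0.05, 0.2)$probe_id
    expect_true(all(callDMPs(st, 0.01, 0.2)$probe_id %in% base))
    expect_true(all(callDMPs(st, 0.05, 0.3)$probe_id %in% base))
    expect_true(all(callDMPs(st, 0.01, 0.3)$probe_id %in% base))
})

test_that("pairwise counting covers all unordered pairs symmetrically", {
    co <- smallCohort(seed = 23, nProbes = 600, n = 4)
    pd <- pairwiseDMPCounts(co$experiment)
    cm <- dmpCounts(pd)
    expect_equal(dim(cm), c(3L, 3L))
    expect_length(pd@sets, 3)
    expect_identical(cm, t(cm))
    expect_true(all(diag(cm) == 0))
    # planted pairs have counts, the unplanted B|C pair shares no probes
    expect_gt(cm["A", "B"], 0)
    expect_gt(cm["A", "C"], 0)
})

test_that("identically generated groups yield zero DMPs", {
    cfg <- syntheticConfig(1000, c(A = 6, B = 6), noiseSd = 0.1,
                           seed = 31)
    co <- generateCohort(cfg)
    pd <- pairwiseDMPCounts(co$experiment)
    expect_equal(dmpCounts(pd)["A", "B"], 0)
})

test_that("counts are invariant to sample order and to constant probes", {
    co <- smallCohort(seed = 29, nProbes = 500, n = 4)
    b <- getBeta(co$experiment)
    sheet <- sampleSheet(co$experiment)
    pd1 <- pairwiseDMPCounts(b, sheet)
    perm <- sample(ncol(b))
    pd2 <- pairwiseDMPCounts(b[, perm], sheet[perm, ])
    expect_equal(dmpCounts(pd1), dmpCounts(pd2)[rownames(dmpCounts(pd1)),
                                                colnames(dmpCounts(pd1))])
    # appending constant probes changes nothing
    const <- matrix(0.42, 50, ncol(b),
                    dimnames = list(sprintf("const%02d", 1:50),
                                    colnames(b)))
    pd3 <- pairwiseDMPCounts(rbind(b, const), sheet)
    expect_equal(dmpCounts(pd3), dmpCounts(pd1))
})

test_that("undersized groups are skipped with a warning", {
    co <- smallCohort(seed = 37, nProbes = 300, n = 3)
    sheet <- sampleSheet(co$experiment)
    sheet$group_label[sheet$sample_id == "C_01"] <- "tiny"
    expect_warning(pd <- pairwiseDMPCounts(getBeta(co$experiment),
                                           sheet), "tiny")
    expect_false("tiny" %in% rownames(dmpCounts(pd)))
    expect_identical(pd@skipped, "tiny")
    expect_error(pairwiseDMPCounts(
        getBeta(co$experiment)[, 1:6],
        data.frame(sample_id = colnames(getBeta(co$experiment))[1:6],
                   group_label = "A")), "2 usable groups")
})
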