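test_that("t-SNE is deterministic for a fixed seed and validates perplexity", {
    co <- smallCohort(seed = 3, nProbes = 500)
    top <- getBeta(co$experiment)
    e1 <- tsneEmbed(top, perplexity = 5, seed = 42)
    e2 <- tsneEmbed(top, perplexity = 5, seed = 42)
    expect_identical(e1$x, e2$x)
    expect_identical(e1$y, e2$y)
    expect_error(tsneEmbed(top, perplexity = 50, seed = 1),
                 "perplexity")
    expect_error(tsneEmbed(top, perplexity = 5), "seed")
})

test_that("duplicated samples embed next to each other", {
    co <- smallCohort(seed = 5, nProbes = 400, n = 10, noiseSd = 0.5)
    b <- getBeta(co$experiment)
    b <- cbind(b, dup = b[, 1])
    colnames(b)[ncol(b)] <- "A_01_dup"
    emb <- tsneEmbed(b, perplexity = 5, seed = 7)
    d <- as.matrix(dist(emb[, c("x", "y")]))
    diag(d) <- Inf
    i <- which(emb$sample_id == "A_01")
    j <- which(emb$sample_id == "A_01_dup")
    # an exact duplicate must be its twin's nearest embedded neighbour,
    # and the pair must sit in the closest tail of all pairwise distances
    expect_equal(which.min(d[i, ]), j, ignore_attr = TRUE)
    expect_lte(d[i, j], quantile(d[upper.tri(d)], 0.05))
})

test_that("well-separated planted groups give high kNN purity", {
    co <- smallCohort(seed = 11, nProbes = 1500)
    emb <- tsneEmbed(getBeta(co$experiment), perplexity = 8, seed = 1)
    labels <- co$groundTruth$clusterAssignment[emb$sample_id]
    expect_gte(knnPurity(emb, labels, k = 5), 0.9)
})

test_that("hierarchical clustering cut at the true k recovers the planted partition", {
    co <- smallCohort(seed = 19, noiseSd = 0.1, nProbes = 800)
    hc <- hierarchicalCluster(getBeta(co$experiment))
    cl <- cutree(hc, k = 3)
    truth <- co$groundTruth$clusterAssignment[names(cl)]
    expect_equal(ari(cl, truth), 1.0)
})

test_that("two samples merge once at their distance; self-correlation distance is 0", {
    set.seed(2)
    m <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    hc <- hierarchicalCluster(m)
    expect_equal(length(hc$height), 1)
    expect_equal(hc$height, 1 - cor(m[, 1], m[, 2]))
    expect_equal(as.numeric(1 - cor(m[, 1], m[, 1])), 0)
    expect_error(hierarchicalCluster(m[, 1, drop = FALSE]),
                 "2 samples")
    m[1, 1] <- NA
    expect_error(hierarchicalCluster(m), "missing")
})

test_that("correlation-distance clustering is invariant to per-sample affine rescaling", {
    set.seed(13)
    m <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
    hc1 <- hierarchicalCluster(m)
    scaled <- sweep(sweep(m, 2, runif(4, 0.5, 3), "*"), 2,
                    rnorm(4), "+")
    hc2 <- hierarchicalCluster(scaled)
    expect_equal(hc1$merge, hc2$merge)
    expect_equal(hc1$height, hc2$height, tolerance = 1e-12)
})

test_that("consensus matrix is symmetric with unit diagonal and valid range", {
    co <- smallCohort(seed = 7, nProbes = 400, n = 6)
    cons <- consensusCluster(getBeta(co$experiment), k = 3, B = 30,
                             seed = 2)
    cm <- consensusMatrix(cons)
    expect_identical(cm, t(cm))
    expect_true(all(diag(cm) == 1))
    v <- cm[!is.na(cm)]
    expect_true(all(v >= 0 & v <= 1))
    expect_error(consensusCluster(getBeta(co$experiment), k = 17,
                                  B = 30, seed = 1), "subsample")
    expect_error(consensusCluster(getBeta(co$experiment), k = 3,
                                  B = 30, subsampleFraction = 0.4),
                 "subsampleFraction")
})

test_that("noise-free well-separated groups give a 0/1 consensus block structure", {
    co <- smallCohort(seed = 9, noiseSd = 0, nProbes = 300, n = 6)
    cons <- consensusCluster(getBeta(co$experiment), k = 3, B = 50,
                             seed = 3)
    cm <- consensusMatrix(cons)
    truth <- co$groundTruth$clusterAssignment[rownames(cm)]
    same <- outer(truth, truth, "==")
    off <- upper.tri(cm) & !is.na(cm)
    expect_true(all(cm[off & same] == 1))
    expect_true(all(cm[off & !same] == 0))
})

test_that("within-group consensus exceeds between-group consensus under noise", {
    co <- smallCohort(seed = 15, noiseSd = 0.3, nProbes = 600, n = 8)
    cons <- consensusCluster(getBeta(co$experiment), k = 3, B = 200,
                             seed = 4)
    cm <- consensusMatrix(cons)
    truth <- co$groundTruth$clusterAssignment[rownames(cm)]
    same <- outer(truth, truth, "==")
    off <- upper.tri(cm) & !is.na(cm)
    expect_gt(mean(cm[off & same], na.rm = TRUE),
              mean(cm[off & !same], na.rm = TRUE))
})

test_that("noise-free consensus entries are invariant to sample order", {
    co <- smallCohort(seed = 25, noiseSd = 0, nProbes = 400, n = 5,
                      nPlanted = 60)
    b <- getBeta(co$experiment)
    c1 <- consensusMatrix(consensusCluster(b, k = 3, B = 40, seed = 5))
    perm <- sample(ncol(b))
    c2 <- consensusMatrix(consensusCluster(b[, perm], k = 3, B = 40,
                                           seed = 6))
    ids <- rownames(c1)
    expect_equal(c1[ids, ids], c2[ids, ids])
})

test_that("an all-ones consensus matrix yields no significant group differences", {
    ids <- c(paste0("R", 1:4), paste0("S", 1:4), paste0("T", 1:4))
    cm <- matrix(1, 12, 12, dimnames = list(ids, ids))
    cons <- new("ConsensusResult", consensus = cm,
                codraws = matrix(10L, 12, 12), B = 10,
                subsampleFraction = 0.8, k = 2, distance = "pearson",
                linkage = "average", seed = 1)
    sheet <- data.frame(sample_id = ids,
                        group_label = rep(c("R", "S", "T"), each = 4))
    tab <- consensusDegreeTest(cons, sheet, "R")
    expect_true(all(!tab$significant))
    expect_true(all(tab$p == 1))
})

test_that("the consensus-degree test separates planted siblings from distant groups", {
    # R and S are planted identically (siblings); T is far from both
    cfg <- syntheticConfig(1500, c(R = 8, S = 8, T = 8),
        plantedDMPs = list(
            list(pair = c("T", "R"), n = 300, delta = 0.4),
            list(pair = c("T", "S"), sameAs = 1)),
        noiseSd = 0.1, seed = 41)
    co <- generateCohort(cfg)
    cons <- consensusCluster(getBeta(co$experiment), k = 2, B = 100,
                             seed = 8)
    tab <- consensusDegreeTest(cons, sampleSheet(co$experiment), "R")
    expect_false(tab$significant[tab$group == "S"])
    expect_true(tab$significant[tab$group == "T"])
})
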