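test_that("ratio features divide paralog reads by DRB1 reads", {
    rc <- data.frame(
        sample_id = c("S1", "S1", "S2", "S3"),
        locus = c("DRB1", "DRB3", "DRB1", "DRB1"),
        reads = c(100L, 50L, 200L, 0L))
    f <- computeRatioFeatures(rc)
    expect_equal(f$ratio_drb3[f$sample_id == "S1"], 0.5)
    expect_equal(f$ratio_drb4[f$sample_id == "S1"], 0)   # missing paralog = 0
    expect_equal(unlist(f[f$sample_id == "S2",
                          c("ratio_drb3", "ratio_drb4", "ratio_drb5")]),
                 c(ratio_drb3 = 0, ratio_drb4 = 0, ratio_drb5 = 0))
    expect_false(f$callable[f$sample_id == "S3"])        # DRB1 = 0 reads
    expect_true(all(is.na(f[f$sample_id == "S3", 2:4])))
})

test_that("kNN separates clean copy-number clusters and breaks ties low", {
    # well-separated ratios at 0 / 0.45 / 0.9 with tiny noise
    set.seed(21)
    n <- 90
    cn <- data.frame(sample_id = sprintf("S%03d", 1:n),
                     drb3 = rep(0:2, each = n / 3),
                     drb4 = 0L, drb5 = 0L)
    feats <- data.frame(
        sample_id = cn$sample_id,
        ratio_drb3 = cn$drb3 * 0.45 + rnorm(n, 0, 0.02),
        ratio_drb4 = 0, ratio_drb5 = 0, callable = TRUE)
    m <- trainCopyNumberModel(feats, cn, seed = 2)
    pred <- predictCopyNumbers(m, feats)
    ho <- pred$sample_id %in% m@holdout
    expect_equal(pred$drb3[ho],
                 cn$drb3[match(pred$sample_id[ho], cn$sample_id)])
    expect_true(all(pred$drb4 == 0L))
    # score vectors are proper vote fractions
    sc <- attr(pred, "scores")$DRB3
    expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)))

    expect_error(trainCopyNumberModel(feats, cn, trainFraction = 1),
                 "holdout")

    # an exact midpoint between a 0-copy and a 1-copy exemplar with k = 2
    # must resolve to the lower copy number
    scores <- hlacomposite:::.knnScores(
        matrix(c(0, 0.45)), factor(c(0, 1), levels = 0:2),
        matrix(0.225), k = 2)
    expect_equal(unname(scores[1, ]), c(0.5, 0.5, 0))
    expect_equal(hlacomposite:::.knnPredict(scores), 0L)
})

test_that("kNN class votes agree with an independent kNN implementation", {
    skip_if_not_installed("FNN")
    set.seed(4)
    x <- matrix(runif(60), ncol = 1)
    y <- factor(rbinom(60, 2, 0.4), levels = 0:2)
    q <- matrix(runif(25), ncol = 1)
    sc <- hlacomposite:::.knnScores(x, y, q, k = 5)
    ours <- hlacomposite:::.knnPredict(sc)
    ref <- as.integer(as.character(FNN::knn(x, q, y, k = 5)))
    # agree wherever the vote is unambiguous (FNN breaks ties at random)
    clear <- apply(sc, 1, function(s) sum(s == max(s)) == 1)
    expect_true(mean(ours[clear] == ref[clear]) > 0.95)
})

test_that("Hand & Till AUC matches brute-force pairwise rank-sums", {
    # perfect separation and pure noise
    s <- diag(3)[c(1, 1, 2, 2, 3, 3), ]; colnames(s) <- 0:2
    expect_equal(handTillAUC(s, c(0, 0, 1, 1, 2, 2)), 1.0)
    flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, 0:2))
    expect_equal(handTillAUC(flat, c(0, 0, 1, 1, 2, 2)), 0.5)
    expect_error(handTillAUC(s, rep(0, 6)), "2 classes")

    # random 3-class toys of <= 8 samples against the exhaustive oracle
    set.seed(13)
    for (rep in 1:25) {
        n <- sample(4:8, 1)
        lab <- c(0:2, sample(0:2, n - 3, replace = TRUE))
        sc <- matrix(round(runif(3 * n), 2), n, 3, dimnames = list(NULL, 0:2))
        expect_equal(handTillAUC(sc, lab), bruteHandTill(sc, lab))
    }
})

test_that("Hand & Till reduces to binary AUC and survives monotone rescaling", {
    set.seed(8)
    n <- 40
    lab <- rbinom(n, 1, 0.5)
    p1 <- plogis(lab + rnorm(n))
    sc <- cbind("0" = 1 - p1, "1" = p1)
    # binary AUC by the rank-sum formula
    r <- rank(p1)
    auc <- (sum(r[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2) /
        (sum(lab) * sum(1 - lab))
    expect_equal(handTillAUC(sc, lab), auc)
    # strictly monotone transform of score columns changes nothing
    sc2 <- cbind("0" = qlogis(pmin(pmax(sc[, 1], 1e-6), 1 - 1e-6)),
                 "1" = sc[, 2]^3)
    expect_equal(handTillAUC(sc2, lab), handTillAUC(sc, lab))
})

test_that("copy-number similarity is the inverted standardized Manhattan", {
    expect_equal(copyNumberSimilarity(c(1, 0, 2), c(1, 0, 2)), 1.0)
    expect_equal(copyNumberSimilarity(c(0, 0, 0), c(2, 2, 2)), 0.0)
    expect_equal(copyNumberSimilarity(c(1, 0, 2), c(1, 1, 2)), 1 - 1 / 6)
    # symmetric; 1 iff identical
    set.seed(5)
    for (i in 1:30) {
        a <- sample(0:2, 3, replace = TRUE); b <- sample(0:2, 3, replace = TRUE)
        expect_equal(copyNumberSimilarity(a, b), copyNumberSimilarity(b, a))
        expect_equal(copyNumberSimilarity(a, b) == 1, all(a == b))
    }
})

test_that("top-n filtering truncates ranked DRB345 calls to the copy number", {
    calls <- makeCallset(list(
        "S1|g|DRB3" = c("DRB3*01:01", "DRB3*02:02"),
        "S1|g|DRB4" = c("DRB4*01:03", "DRB4*01:01"),
        "S1|g|DRB5" = c("DRB5*01:01"),
        "S1|g|A" = c("A*01:01", "A*02:01")), ranked = TRUE)
    cn <- data.frame(sample_id = "S1", drb3 = 0L, drb4 = 1L, drb5 = 2L)
    filt <- callTable(filterGenotypeByCopyNumber(calls, cn))
    expect_true(all(is.na(
        unlist(filt[filt$locus == "DRB3", c("allele1", "allele2")]))))
    expect_equal(filt$allele1[filt$locus == "DRB4"], "DRB4*01:03")  # rank head
    expect_true(is.na(filt$allele2[filt$locus == "DRB4"]))
    expect_equal(filt$allele1[filt$locus == "DRB5"], "DRB5*01:01")  # unchanged
    expect_equal(filt$allele1[filt$locus == "A"], "A*01:01")        # untouched

    # unranked callsets cannot be truncated
    unr <- makeCallset(list("S1|g|DRB3" = c("DRB3*01:01", "DRB3*02:02")),
                       ranked = FALSE)
    expect_error(filterGenotypeByCopyNumber(
        unr, data.frame(sample_id = "S1", drb3 = 1L, drb4 = 0L, drb5 = 0L)),
        "ranked")
    # no truncation needed: unranked is fine
    expect_silent(filterGenotypeByCopyNumber(
        unr, data.frame(sample_id = "S1", drb3 = 2L, drb4 = 0L, drb5 = 0L)))
})

test_that("impossible predicted vectors are flagged, not repaired", {
    set.seed(30)
    n <- 60
    cn <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     drb3 = rep(0:2, each = n / 3),
                     drb4 = rep(0:2, times = n / 3), drb5 = 0L)
    feats <- data.frame(sample_id = cn$sample_id,
                        ratio_drb3 = cn$drb3 * 0.45 + rnorm(n, 0, 0.02),
                        ratio_drb4 = cn$drb4 * 0.45 + rnorm(n, 0, 0.02),
                        ratio_drb5 = 0, callable = TRUE)
    m <- trainCopyNumberModel(feats, cn, seed = 6)
    pred <- predictCopyNumbers(m, feats)
    expect_equal(pred$valid, pred$drb3 + pred$drb4 + pred$drb5 <= 2)
    expect_true(any(!pred$valid))   # this design plants 2+2 vectors
})
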