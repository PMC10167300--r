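test_that("cohorts respect DRB1-paralog linkage and diploidy", {
    cfg <- simulationConfig(nSamples = 120, seed = 3)
    cohort <- simulateCohort(cfg)
    cn <- cohort$copyNumbers
    expect_true(all(cn$drb3 + cn$drb4 + cn$drb5 <= 2))
    tdf <- callTable(cohort$truth)
    # every classical locus has exactly two truth alleles per sample
    classical <- tdf[!tdf$locus %in% c("DRB3", "DRB4", "DRB5"), ]
    expect_true(all(!is.na(classical$allele1) & !is.na(classical$allele2)))
    # paralog truth rows exist for every sample and agree with copy numbers
    for (p in c("drb3", "drb4", "drb5")) {
        rows <- tdf[tdf$locus == toupper(p), ]
        rows <- rows[match(cn$sample_id, rows$sample_id), ]
        nAll <- (!is.na(rows$allele1)) + (!is.na(rows$allele2))
        expect_equal(nAll, cn[[p]])
    }
    # the DRB1 genotype's linked groups explain the copy-number vector
    linkage <- c("01" = "none", "03" = "DRB3", "04" = "DRB4", "07" = "DRB4",
                 "08" = "none", "09" = "DRB4", "10" = "none", "11" = "DRB3",
                 "13" = "DRB3", "14" = "DRB3", "15" = "DRB5", "16" = "DRB5")
    drb1 <- tdf[tdf$locus == "DRB1", ]
    for (i in seq_len(20)) {
        grp <- substr(sub(".*\\*", "", c(drb1$allele1[i], drb1$allele2[i])),
                      1, 2)
        want <- table(factor(linkage[grp], levels = c("DRB3", "DRB4", "DRB5")))
        expect_equal(unname(unlist(
            cn[cn$sample_id == drb1$sample_id[i],
               c("drb3", "drb4", "drb5")])),
            as.integer(want))
    }
})

test_that("DRB5-haplotype frequency propagates to cohort prevalence", {
    cfg <- simulationConfig(nSamples = 400, seed = 13)
    cohort <- simulateCohort(cfg)
    pool <- cohort$pools$DRB1
    linkage <- c("01" = "none", "03" = "DRB3", "04" = "DRB4", "07" = "DRB4",
                 "08" = "none", "09" = "DRB4", "10" = "none", "11" = "DRB3",
                 "13" = "DRB3", "14" = "DRB3", "15" = "DRB5", "16" = "DRB5")
    p5 <- sum(pool$freq[linkage[pool$group] == "DRB5"])
    want <- 1 - (1 - p5)^2
    got <- mean(cohort$copyNumbers$drb5 >= 1)
    expect_lt(abs(got - want), 3 * sqrt(want * (1 - want) / 400))
})

test_that("zero error reproduces truth; total dropout empties the callset", {
    cfgPerfect <- simulationConfig(nSamples = 25, seed = 7,
        genotypers = list(perfect = list(
            substitution = c(0, 0, 0), dropout = 0, spurious = 0,
            maxFields = 3, repertoire = c("A", "B", "DRB1"))))
    sim <- simulateAll(cfgPerfect)
    cc <- summarizeConcordance(sim$calls, sim$truth, 1:3)
    cc <- cc[cc$assessed, ]
    expect_true(all(cc$mean_accuracy == 1))
    expect_true(all(cc$mean_success == 1))

    cfgDrop <- simulationConfig(nSamples = 25, seed = 7,
        genotypers = list(gone = list(
            substitution = c(0, 0, 0), dropout = 1, spurious = 0,
            maxFields = 3, repertoire = c("A", "B", "DRB1"))))
    simD <- simulateAll(cfgDrop)
    ccD <- summarizeConcordance(simD$calls, simD$truth, 2)
    ccD <- ccD[ccD$assessed, ]
    expect_true(all(ccD$mean_accuracy == 0))
    expect_true(all(is.na(ccD$mean_success)))
})

test_that("read counts carry the planted per-copy ratio signal", {
    cfg <- simulationConfig(nSamples = 300, seed = 19)
    cohort <- simulateCohort(cfg)
    rc <- simulateReadCounts(cohort$copyNumbers, cfg)
    feats <- computeRatioFeatures(rc)
    m <- merge(feats, cohort$copyNumbers, by = "sample_id")
    # the generator truncates negative ratios at zero, so the expected
    # class mean is that of a left-truncated Normal(cp * 0.45, 0.05^2):
    # E[max(0, Y)] = m pnorm(m / s) + s dnorm(m / s)
    for (cp in 0:2) {
        sel <- m$drb3 == cp
        if (sum(sel) < 10) next
        mu <- cp * 0.45; s <- 0.05
        want <- mu * pnorm(mu / s) + s * dnorm(mu / s)
        expect_lt(abs(mean(m$ratio_drb3[sel]) - want), 0.02)
    }
    # dispersion 0 and noise 0 -> deterministic counts
    cfg0 <- simulationConfig(nSamples = 10, seed = 19,
        readDepth = list(meanReads = 500, dispersion = 0, perCopyRatio = 0.4,
                         ratioNoiseSd = 0, background = 0))
    cn0 <- simulateCohort(cfg0)$copyNumbers
    rc0 <- simulateReadCounts(cn0, cfg0)
    expect_true(all(rc0$reads[rc0$locus == "DRB1"] == 500))
    drb3 <- rc0$reads[rc0$locus == "DRB3"]
    expect_equal(drb3, as.integer(round(cn0$drb3 * 0.4 * 500)))
})

test_that("generators are byte-identical under a fixed seed", {
    cfg <- simulationConfig(nSamples = 15, seed = 99)
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    simulateAll(cfg, dir = d1)
    simulateAll(cfg, dir = d2)
    for (f in list.files(d1)) {
        b1 <- readBin(file.path(d1, f), "raw", n = 5e6)
        b2 <- readBin(file.path(d2, f), "raw", n = 5e6)
        expect_identical(b1, b2)
    }
    # a different seed changes the cohort
    d3 <- file.path(tempdir(), "simC")
    simulateAll(simulationConfig(nSamples = 15, seed = 100), dir = d3)
    expect_false(identical(
        readBin(file.path(d1, "truth.tsv"), "raw", n = 5e6),
        readBin(file.path(d3, "truth.tsv"), "raw", n = 5e6)))
})

test_that("simulated files round-trip through the package readers", {
    cfg <- simulationConfig(nSamples = 12, seed = 55)
    d <- file.path(tempdir(), "simRT")
    sim <- simulateAll(cfg, dir = d)
    truth2 <- readGenotypeTable(file.path(d, "truth.tsv"), ranked = TRUE)
    expect_equal(callTable(truth2), callTable(sim$truth))
    calls2 <- readGenotypeTable(file.path(d, "calls.tsv"), ranked = TRUE)
    expect_equal(callTable(calls2), callTable(sim$calls))
    rc2 <- readReadCounts(file.path(d, "read_counts.tsv"))
    expect_equal(rc2, sim$readCounts)
    cells2 <- readCellCounts(file.path(d, "cell_counts.tsv"))
    expect_equal(cells2$count_allele1, sim$cellCounts$count_allele1)
    msa2 <- Biostrings::readDNAStringSet(file.path(d, "msa.fasta"))
    expect_equal(as.character(msa2), as.character(sim$msa))
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(nSamples = 0))
    expect_error(simulationConfig(genotypers = list(
        bad = list(substitution = c(2, 0, 0), dropout = 0, spurious = 0,
                   maxFields = 2, repertoire = "A"))))
})
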