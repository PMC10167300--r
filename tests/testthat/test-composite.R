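test_that("selector instances carry availability and best-accuracy labels", {
    truth <- makeCallset(list(
        "S1|truth|A" = c("A*01:01", "A*02:01"),
        "S1|truth|DPB1" = c("DPB1*01:01", "DPB1*02:01")))
    calls <- makeCallset(list(
        "S1|arcasHLA|A" = c("A*01:01", "A*03:01"),
        "S1|OptiType|A" = c("A*01:01", "A*02:01"),
        "S1|arcasHLA|DPB1" = c("DPB1*01:01", "DPB1*02:01")))
    inst <- buildSelectorInstances(calls, truth, fieldLevels = 2)
    a <- inst[inst$locus == "A", ]
    expect_true(a$avail_arcasHLA && a$avail_OptiType)
    expect_equal(a$label, "OptiType")          # accuracy 1.0 beats 0.5
    dp <- inst[inst$locus == "DPB1", ]
    expect_equal(dp$label, "arcasHLA")         # only candidate
    expect_false(dp$avail_OptiType)

    # ties resolve by the fixed priority order (arcasHLA first)
    tie <- makeCallset(list(
        "S1|OptiType|A" = c("A*01:01", "A*02:01"),
        "S1|arcasHLA|A" = c("A*01:01", "A*02:01")))
    instT <- buildSelectorInstances(tie, truth, fieldLevels = 2)
    expect_equal(instT$label[instT$locus == "A"], "arcasHLA")
})

test_that("a planted locus rule is learned exactly; guards fire", {
    # the best genotyper is determined exactly by locus class: G1 covers all
    # loci with moderate error, G2 only class II but nearly perfectly.  With
    # G2 first in the tie-break priority the labels follow the locus class
    # deterministically, a rule the tree can express, so holdout selection
    # should be (near) perfect
    cfg <- simulationConfig(
        nSamples = 120, seed = 17,
        genotypers = list(
            G1 = list(substitution = c(0.1, 0.1, 0), dropout = 0,
                      spurious = 0, maxFields = 2,
                      repertoire = c("A", "B", "C", "DQA1", "DQB1")),
            G2 = list(substitution = c(0.005, 0.005, 0), dropout = 0,
                      spurious = 0, maxFields = 2,
                      repertoire = c("DQA1", "DQB1"))))
    sim <- simulateAll(cfg)
    inst <- buildSelectorInstances(sim$calls, sim$truth, fieldLevels = 2,
                                   priority = c("G2", "G1"))
    sel <- trainSelector(inst, seed = 17)
    ho <- inst[inst$sample_id %in% sel@holdout, ]
    pick <- predictSelector(sel, ho)
    want <- ifelse(ho$locus %in% c("A", "B", "C"), "G1", "G2")
    expect_gt(mean(pick == want), 0.98)
    expect_gt(sel@holdoutAUC, 0.95)

    expect_error(trainSelector(inst, trainFraction = 1), "holdout")
})

test_that("a degenerate single-label cohort yields a constant model", {
    truth <- makeCallset(stats::setNames(
        lapply(1:12, function(i) c("A*01:01", "A*02:01")),
        sprintf("S%d|truth|A", 1:12)))
    calls <- makeCallset(stats::setNames(
        lapply(1:12, function(i) c("A*01:01", "A*02:01")),
        sprintf("S%d|only|A", 1:12)))
    inst <- buildSelectorInstances(calls, truth, fieldLevels = 2)
    sel <- trainSelector(inst, seed = 1)
    expect_match(paste(sel@notes, collapse = " "), "single label")
    expect_true(all(predictSelector(sel, inst) == "only"))
})

test_that("composite copies the selected call and falls back on dropout", {
    truth <- makeCallset(list(
        "S1|truth|A" = c("A*01:01", "A*02:01"),
        "S2|truth|A" = c("A*01:01", "A*02:01")))
    calls <- makeCallset(list(
        "S1|arcasHLA|A" = c("A*01:01", "A*03:01"),
        "S1|OptiType|A" = c("A*01:01", "A*02:01"),
        "S2|arcasHLA|A" = c("A*01:01", "A*02:01")))  # OptiType absent at S2
    inst <- buildSelectorInstances(calls, truth, fieldLevels = 2)
    sel <- trainSelector(inst, trainFraction = 0.5, seed = 2)
    comp <- assembleComposite(calls, sel, fieldLevel = 2)
    cdf <- callTable(comp)
    expect_equal(unique(cdf$genotyper), "composite(aO)")
    # S2: whatever the tree says, only arcasHLA is available
    s2 <- cdf[cdf$sample_id == "S2", ]
    expect_equal(sort(c(s2$allele1, s2$allele2)), c("A*01:01", "A*02:01"))

    # all genotypers absent at a slot -> an empty composite call
    calls3 <- makeCallset(list(
        "S1|arcasHLA|A" = c("A*01:01", "A*03:01"),
        "S1|arcasHLA|B" = character(0),
        "S2|arcasHLA|A" = c("A*01:01", "A*02:01")))
    comp3 <- assembleComposite(calls3, trainSelector(
        buildSelectorInstances(calls3, truth, 2), trainFraction = 0.5,
        seed = 3), 2)
    b <- callTable(comp3)
    expect_true(is.na(b$allele1[b$locus == "B"]))
})

test_that("composite of a single genotyper reproduces its calls", {
    cfg <- simulationConfig(nSamples = 30, seed = 23,
        genotypers = list(
            solo = list(substitution = c(0.05, 0.1, 0), dropout = 0.05,
                        spurious = 0, maxFields = 2,
                        repertoire = c("A", "B", "C"))))
    sim <- simulateAll(cfg)
    inst <- buildSelectorInstances(sim$calls, sim$truth, 2)
    sel <- trainSelector(inst, seed = 23)
    comp <- assembleComposite(sim$calls, sel, 2)
    orig <- callTable(sim$calls)
    got <- callTable(comp)
    key <- function(d) d[order(d$sample_id, d$locus),
                         c("sample_id", "locus", "allele1", "allele2")]
    expect_equal(key(got), key(key(orig)), ignore_attr = TRUE)
})

test_that("learned composite tracks the per-locus best genotyper", {
    cfg <- simulationConfig(
        nSamples = 200, seed = 31,
        genotypers = list(
            G1 = list(substitution = c(0.02, 0.05, 0), dropout = 0.02,
                      spurious = 0, maxFields = 2,
                      repertoire = c("A", "B", "C", "DRB1", "DQB1"),
                      locusError = c(DRB1 = 8, DQB1 = 8)),
            G2 = list(substitution = c(0.02, 0.05, 0), dropout = 0.02,
                      spurious = 0, maxFields = 2,
                      repertoire = c("A", "B", "C", "DRB1", "DQB1"),
                      locusError = c(A = 8, B = 8, C = 8)),
            G3 = list(substitution = c(0.08, 0.15, 0), dropout = 0.10,
                      spurious = 0, maxFields = 2,
                      repertoire = c("A", "B", "C", "DRB1", "DQB1"))))
    sim <- simulateAll(cfg)
    inst <- buildSelectorInstances(sim$calls, sim$truth, 2)
    sel <- trainSelector(inst, seed = 31)
    comp <- assembleComposite(sim$calls, sel, 2)

    hold <- function(cs) {
        df <- callTable(cs)
        GenotypeCallset(df[df$sample_id %in% sel@holdout, ],
                        ranked = isRanked(cs))
    }
    ccC <- summarizeConcordance(hold(comp), hold(sim$truth), 2)
    ccG <- summarizeConcordance(hold(sim$calls), hold(sim$truth), 2)
    compAcc <- mean(ccC$mean_accuracy, na.rm = TRUE)
    for (g in c("G1", "G2", "G3"))
        expect_gte(compAcc, meanAcc(ccG, g, 2) - 0.02)

    # oracle bound: a cheating selector that always picks the most accurate
    # available genotyper is at least as good as the learned composite
    instHo <- inst[inst$sample_id %in% sel@holdout & inst$field_level == 2, ]
    oracleAcc <- mean(instHo$best_accuracy)
    expect_gte(oracleAcc + 1e-9, compAcc)
})
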