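.CLASSICAL_LOCI <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

# simplified DRB1 allele-group -> linked paralog table. Real haplotypes link
# DRB1*03/11/13/14 to DRB3, *04/07/09 to DRB4, *15/16 to DRB5 and *01/08/10
# to no paralog; the synthetic pool reuses those group digits. This is an
# emulation sufficient to produce valid copy-number vectors, not a
# population-genetics model.
.DRB_LINKAGE <- c("01" = "none", "03" = "DRB3", "04" = "DRB4", "07" = "DRB4",
                  "08" = "none", "09" = "DRB4", "10" = "none", "11" = "DRB3",
                  "13" = "DRB3", "14" = "DRB3", "15" = "DRB5", "16" = "DRB5")

#' Simulation configuration
#'
#' Assembles the full parameter set for the synthetic cohort generator with
#' defaults emulating a 5'-based pseudobulk scRNA-seq benchmarking cohort:
#' 157 diploid samples, four genotypers with distinct repertoires and error
#' profiles, DRB1-linked DRB3/4/5 copy numbers, read counts whose
#' paralog/DRB1 ratio is centred on 0.45 per copy with Gaussian noise
#' (sd 0.05), and per-cell biallelic counts with planted log-odds.
#'
#' @param nSamples cohort size (default 157).
#' @param poolSize alleles per locus in the synthetic pool (default 20).
#' @param seed master seed; every generator draws from it deterministically.
#' @param genotypers named list of per-genotyper error models; each entry
#'   has `substitution` (per-field rates, length 3), `dropout` (per-allele),
#'   `spurious` (extra DRB345 allele rate), `maxFields`, `repertoire`, and
#'   optionally `locusError`, a named numeric vector of per-locus
#'   multipliers applied to the substitution and dropout rates (capped at
#'   1) so that a genotyper's reliability can differ by locus.
#' @param readDepth list: `meanReads`, `dispersion` (0 = deterministic),
#'   `perCopyRatio`, `ratioNoiseSd`, `background`.
#' @param ase list: `groups` (data.frame with `group`, `mu`, `tau2`,
#'   `n_cells`), `readsPerCell`, `readDispersion`.
#' @param msa list: `nSeqs`, `length`, `hotspotFraction`, `conservedMutRate`,
#'   `gapRate`.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    nSamples = 157L,
    poolSize = 20L,
    seed = 1L,
    genotypers = list(
        arcasHLA = list(substitution = c(0.02, 0.08, 0.15), dropout = 0.02,
                        spurious = 0.50, maxFields = 3L,
                        repertoire = c(.CLASSICAL_LOCI, .PARALOGS)),
        OptiType = list(substitution = c(0.01, 0.05, 0.00), dropout = 0.05,
                        spurious = 0, maxFields = 2L,
                        repertoire = c("A", "B", "C")),
        PHLAT    = list(substitution = c(0.03, 0.10, 0.20), dropout = 0.03,
                        spurious = 0, maxFields = 3L,
                        repertoire = setdiff(.CLASSICAL_LOCI,
                                             c("DPA1", "DPB1"))),
        HLAminer = list(substitution = c(0.10, 0.25, 0.35), dropout = 0.15,
                        spurious = 0.70, maxFields = 3L,
                        repertoire = c(.CLASSICAL_LOCI, .PARALOGS))),
    readDepth = list(meanReads = 1000, dispersion = 0.2, perCopyRatio = 0.45,
                     ratioNoiseSd = 0.05, background = 0),
    ase = list(groups = data.frame(group = c("mono", "cDC", "Tcell"),
                                   mu = c(0, log(2), log(3)),
                                   tau2 = c(0.05, 0.05, 0.05),
                                   n_cells = c(200L, 200L, 200L)),
               readsPerCell = 20, readDispersion = 2),
    msa = list(nSeqs = 30L, length = 600L, hotspotFraction = 0.4,
               conservedMutRate = 0.02, gapRate = 0.05)) {
    cfg <- list(nSamples = as.integer(nSamples), poolSize = as.integer(poolSize),
                seed = as.integer(seed), genotypers = genotypers,
                readDepth = readDepth, ase = ase, msa = msa)
    rates <- c(unlist(lapply(genotypers, function(g)
        c(g$substitution, g$dropout, g$spurious))))
    stopifnot(all(rates >= 0 & rates <= 1), cfg$nSamples >= 1L,
              cfg$poolSize >= 2L, !is.na(cfg$seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

# haplotype-group masses for the DRB1 pool, roughly matching European
# cohort prevalences of the linked paralogs (DRB3 ~ 1/3 of haplotypes,
# DRB5 ~ 15%); within a paralog group allele frequencies decay geometrically
.DRB_GROUP_MASS <- c(none = 0.28, DRB3 = 0.33, DRB4 = 0.24, DRB5 = 0.15)

# synthetic allele pool for one locus: names inside the IMGT grammar but
# with invented digits; frequencies decay geometrically like real cohorts
.allelePool <- function(locus, poolSize) {
    if (locus == "DRB1") {
        groups <- rep_len(names(.DRB_LINKAGE), poolSize)
        w <- 0.6^(seq_len(poolSize) - 1L)
        linked <- .DRB_LINKAGE[groups]
        freq <- numeric(poolSize)
        for (p in names(.DRB_GROUP_MASS)) {
            sel <- linked == p
            if (any(sel))
                freq[sel] <- .DRB_GROUP_MASS[[p]] * w[sel] / sum(w[sel])
        }
    } else {
        groups <- sprintf("%02d", ((seq_len(poolSize) - 1L) %% 30L) + 60L)
        freq <- 0.6^(seq_len(poolSize) - 1L)
    }
    name <- sprintf("%s*%s:%02d:%02d", locus, groups,
                    ((seq_len(poolSize) - 1L) %/% length(unique(groups))) + 1L,
                    (seq_len(poolSize) %% 4L) + 1L)
    data.frame(allele = name, group = groups, freq = freq / sum(freq))
}

#' Simulate a diploid cohort with DRB1-linked paralog copy numbers
#'
#' Draws two alleles per classical locus per sample from a
#' frequency-weighted synthetic pool.  Each DRB1 haplotype carries the
#' paralog (DRB3/4/5 or none) linked to its allele group, and one allele of
#' that paralog; copy numbers derive from the two haplotypes, so
#' `drb3 + drb4 + drb5 <= 2` always.  Truth rows are emitted for all three
#' paralogs, with empty calls where the copy number is zero.
#'
#' @param config a [simulationConfig()].
#' @return list with `truth` (a [GenotypeCallset-class], genotyper
#'   `"truth"`), `copyNumbers` (data.frame `sample_id`, `drb3`, `drb4`,
#'   `drb5`), and `pools` (the allele pools used).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    pools <- lapply(stats::setNames(nm = c(.CLASSICAL_LOCI, .PARALOGS)),
                    .allelePool, poolSize = config$poolSize)
    samples <- sprintf("S%03d", seq_len(config$nSamples))
    rows <- list(); cn <- list()
    for (s in samples) {
        for (l in setdiff(.CLASSICAL_LOCI, "DRB1")) {
            al <- sample(pools[[l]]$allele, 2L, replace = TRUE,
                         prob = pools[[l]]$freq)
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = s, genotyper = "truth", locus = l,
                allele1 = al[1L], allele2 = al[2L])
        }
        hap <- sample(seq_len(nrow(pools$DRB1)), 2L, replace = TRUE,
                      prob = pools$DRB1$freq)
        drb1 <- pools$DRB1$allele[hap]
        linked <- .DRB_LINKAGE[pools$DRB1$group[hap]]
        rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, genotyper = "truth", locus = "DRB1",
            allele1 = drb1[1L], allele2 = drb1[2L])
        cnv <- c(DRB3 = 0L, DRB4 = 0L, DRB5 = 0L)
        parAl <- list(DRB3 = character(0L), DRB4 = character(0L),
                      DRB5 = character(0L))
        for (h in 1:2) {
            p <- linked[h]
            if (p == "none") next
            cnv[p] <- cnv[p] + 1L
            parAl[[p]] <- c(parAl[[p]],
                            sample(pools[[p]]$allele, 1L,
                                   prob = pools[[p]]$freq))
        }
        for (p in .PARALOGS) {
            al <- parAl[[p]]
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = s, genotyper = "truth", locus = p,
                allele1 = if (length(al) >= 1L) al[1L] else NA_character_,
                allele2 = if (length(al) >= 2L) al[2L] else NA_character_)
        }
        cn[[length(cn) + 1L]] <- data.frame(
            sample_id = s, drb3 = cnv[["DRB3"]], drb4 = cnv[["DRB4"]],
            drb5 = cnv[["DRB5"]])
    }
    list(truth = GenotypeCallset(do.call(rbind, rows), ranked = TRUE),
         copyNumbers = do.call(rbind, cn),
         pools = pools)
}

# mutate one field of an allele name to a different random 2-digit value
.mutateField <- function(allele, field, pool) {
    a <- parseAllele(allele)
    f <- alleleFields(a)[[1L]]
    if (field == 1L) {      # field-1 error: re-draw the allele group
        other <- setdiff(pool$allele, allele)
        if (!length(other)) return(allele)
        return(sample(other, 1L))
    }
    if (length(f) < field) return(allele)
    repeat {
        new <- sprintf("%02d", sample.int(99L, 1L))
        if (new != f[field]) break
    }
    f[field] <- new
    paste0(alleleLocus(a), "*", paste(f, collapse = ":"))
}

#' Simulate genotyper callsets with configurable error and dropout
#'
#' Emulates the output of upstream HLA genotypers on a known cohort.  Per
#' genotyper x locus x allele: the call is dropped with the dropout
#' probability; otherwise each field may be substituted (a field-1 error
#' re-draws the allele group, deeper errors keep the prefix).  DRB345 calls
#' optionally gain spurious extra paralog alleles (the false-positive mode
#' that top-n copy-number filtering corrects); ranks put true-derived
#' alleles before spurious ones.  Calls are truncated to the genotyper's
#' `maxFields` and restricted to its locus repertoire.
#'
#' @param cohort result of [simulateCohort()].
#' @param config a [simulationConfig()].
#' @return a ranked [GenotypeCallset-class] holding all simulated
#'   genotypers.
#' @export
simulateCallset <- function(cohort, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1L)
    tdf <- callTable(cohort$truth)
    pools <- cohort$pools
    rows <- list()
    for (g in names(config$genotypers)) {
        gp <- config$genotypers[[g]]
        sub <- gp$substitution
        for (i in seq_len(nrow(tdf))) {
            l <- tdf$locus[i]
            if (!l %in% gp$repertoire) next
            mult <- 1
            if (!is.null(gp$locusError) && l %in% names(gp$locusError))
                mult <- gp$locusError[[l]]
            subL <- pmin(1, sub * mult)
            dropL <- min(1, gp$dropout * mult)
            called <- character(0L)
            for (al in stats::na.omit(c(tdf$allele1[i], tdf$allele2[i]))) {
                if (stats::runif(1L) < dropL) next
                for (f in seq_along(subL))
                    if (subL[f] > 0 && stats::runif(1L) < subL[f])
                        al <- .mutateField(al, f, pools[[l]])
                called <- c(called, truncateAllele(al, gp$maxFields))
            }
            if (l %in% .PARALOGS && gp$spurious > 0 && length(called) < 2L &&
                stats::runif(1L) < gp$spurious)
                called <- c(called,
                            truncateAllele(sample(pools[[l]]$allele, 1L),
                                           gp$maxFields))
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = tdf$sample_id[i], genotyper = g, locus = l,
                allele1 = if (length(called) >= 1L) called[1L] else NA_character_,
                allele2 = if (length(called) >= 2L) called[2L] else NA_character_)
        }
    }
    GenotypeCallset(do.call(rbind, rows), ranked = TRUE)
}

#' Simulate locus-level mapped-read counts
#'
#' DRB1 reads follow a gamma-mixed (negative binomial) count model;
#' each paralog's reads are the DRB1 reads times a per-sample ratio drawn
#' around `copy x perCopyRatio` with Gaussian noise, truncated at zero.
#' With `dispersion = 0` and `ratioNoiseSd = 0` the counts are
#' deterministic.
#'
#' @param copyNumbers data.frame from [simulateCohort()].
#' @param config a [simulationConfig()].
#' @return data.frame with columns `sample_id`, `locus`, `reads`.
#' @export
simulateReadCounts <- function(copyNumbers, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 2L)
    rd <- config$readDepth
    n <- nrow(copyNumbers)
    drb1 <- if (rd$dispersion <= 0) rep(round(rd$meanReads), n)
            else stats::rnbinom(n, mu = rd$meanReads, size = 1 / rd$dispersion)
    rows <- data.frame(sample_id = copyNumbers$sample_id, locus = "DRB1",
                       reads = as.integer(drb1))
    for (p in .PARALOGS) {
        copies <- copyNumbers[[tolower(p)]]
        ratio <- copies * rd$perCopyRatio +
            if (rd$ratioNoiseSd > 0) stats::rnorm(n, 0, rd$ratioNoiseSd)
            else 0
        reads <- as.integer(round(pmax(0, ratio) * drb1 + rd$background))
        rows <- rbind(rows, data.frame(sample_id = copyNumbers$sample_id,
                                       locus = p, reads = reads))
    }
    rownames(rows) <- NULL
    rows
}

#' Simulate per-cell biallelic counts with planted ASE
#'
#' Per group g with planted mean log-odds `mu` and between-cell variance
#' `tau2`: each cell draws a true log-odds from Normal(mu, tau2), a total
#' read count from a negative binomial, and allele-1 reads from a binomial
#' with probability `plogis(theta)`.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns `cell_id`, `group`, `count_allele1`,
#'   `count_allele2`; planted parameters attached as attribute `"truth"`.
#' @export
simulateCellCounts <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 3L)
    gs <- config$ase$groups
    out <- list()
    for (i in seq_len(nrow(gs))) {
        n <- gs$n_cells[i]
        theta <- stats::rnorm(n, gs$mu[i], sqrt(gs$tau2[i]))
        total <- stats::rnbinom(n, mu = config$ase$readsPerCell,
                                size = config$ase$readDispersion)
        a1 <- stats::rbinom(n, total, stats::plogis(theta))
        out[[i]] <- data.frame(
            cell_id = sprintf("%s_c%04d", gs$group[i], seq_len(n)),
            group = gs$group[i], count_allele1 = a1,
            count_allele2 = total - a1)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- gs
    res
}

#' Simulate a toy HLA allele alignment
#'
#' Generates an aligned set of allele sequences with a high-diversity 5'
#' block (echoing the concentration of HLA polymorphism in the
#' peptide-binding-groove exons), a conserved 3' remainder with sparse
#' mutations, and gap runs mimicking partially sequenced reference alleles.
#'
#' @param config a [simulationConfig()].
#' @return a [Biostrings::DNAStringSet] of equal-width sequences.
#' @export
simulateMsa <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 4L)
    m <- config$msa
    L <- m$length; n <- m$nSeqs
    hot <- seq_len(round(L * m$hotspotFraction))
    consensus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
        s <- consensus
        s[hot] <- sample(c("A", "C", "G", "T"), length(hot), replace = TRUE)
        cold <- setdiff(seq_len(L), hot)
        mut <- cold[stats::runif(length(cold)) < m$conservedMutRate]
        if (length(mut))
            s[mut] <- sample(c("A", "C", "G", "T"), length(mut),
                             replace = TRUE)
        if (stats::runif(1L) < m$gapRate * 4) {   # partial 3' sequence
            from <- sample(seq(round(L * 0.7), L), 1L)
            s[from:L] <- "-"
        }
        seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- sprintf("HLA*%02d:%02d", seq_len(n), (seq_len(n) %% 9L) + 1L)
    Biostrings::DNAStringSet(seqs)
}

#' Run every generator and optionally write the pipeline's input files
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory; when given, writes `truth.tsv`,
#'   `calls.tsv`, `read_counts.tsv`, `cell_counts.tsv` and `msa.fasta`.
#' @return list with `truth`, `copyNumbers`, `calls`, `readCounts`,
#'   `cellCounts`, `msa`, `config`.
#' @export
simulateAll <- function(config = simulationConfig(), dir = NULL) {
    cohort <- simulateCohort(config)
    calls <- simulateCallset(cohort, config)
    readCounts <- simulateReadCounts(cohort$copyNumbers, config)
    cellCounts <- simulateCellCounts(config)
    msa <- simulateMsa(config)
    sim <- list(truth = cohort$truth, copyNumbers = cohort$copyNumbers,
                calls = calls, readCounts = readCounts,
                cellCounts = cellCounts, msa = msa, config = config)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeGenotypeTable(cohort$truth, file.path(dir, "truth.tsv"))
        writeGenotypeTable(calls, file.path(dir, "calls.tsv"))
        utils::write.table(cohort$copyNumbers,
                           file.path(dir, "copy_numbers.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(readCounts, file.path(dir, "read_counts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cellCounts, file.path(dir, "cell_counts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        Biostrings::writeXStringSet(msa, file.path(dir, "msa.fasta"))
    }
    sim
}
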