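#' Read a genotype table
#'
#' Canonical genotype exchange format: a tab-delimited table with header
#' `sample_id`, `genotyper`, `locus`, `allele1`, `allele2`; an empty cell
#' is an absent allele call.  Every allele string is validated against the
#' colon-delimited HLA nomenclature, with the offending row reported.
#'
#' @param path TSV file path.
#' @param ranked logical; declare that the allele columns are in the
#'   upstream genotyper's rank order (required for top-n filtering).
#' @return a [GenotypeCallset-class].
#' @export
readGenotypeTable <- function(path, ranked = FALSE) {
    df <- utils::read.delim(path, colClasses = "character",
                            na.strings = c("", "NA"))
    missing <- setdiff(.CALL_COLS, names(df))
    if (length(missing))
        stop(sprintf("'%s' lacks column(s): %s", path,
                     paste(missing, collapse = ", ")))
    for (col in c("allele1", "allele2")) {
        al <- df[[col]]
        bad <- which(!is.na(al) & !vapply(al, function(s) {
            if (is.na(s)) return(TRUE)
            !inherits(try(parseAllele(s), silent = TRUE), "try-error")
        }, logical(1L)))
        if (length(bad))
            stop(sprintf("'%s' row %d: malformed allele '%s'",
                         path, bad[1L], al[bad[1L]]))
    }
    key <- paste(df$sample_id, df$genotyper, df$locus)
    if (anyDuplicated(key))
        stop(sprintf("'%s' row %d: duplicated sample x genotyper x locus",
                     path, which(duplicated(key))[1L]))
    GenotypeCallset(df, ranked = ranked)
}

#' Write a genotype table
#'
#' @param callset a [GenotypeCallset-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(callset, path) {
    stopifnot(is(callset, "GenotypeCallset"))
    df <- callTable(callset)
    df[is.na(df)] <- ""
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a locus read-count table (`sample_id`, `locus`, `reads`)
#' @param path TSV file path.
#' @return data.frame.
#' @export
readReadCounts <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "locus", "reads") %in% names(df)))
    df$reads <- as.integer(df$reads)
    df
}

#' Read a per-cell biallelic count table
#' (`cell_id`, `group`, `count_allele1`, `count_allele2`)
#' @param path TSV file path.
#' @return data.frame.
#' @export
readCellCounts <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("cell_id", "count_allele1", "count_allele2") %in%
                  names(df)))
    df
}

#' Run the full benchmarking pipeline on simulated inputs
#'
#' Orders the package's stages in benchmarking order: simulate the
#' cohort and callsets, score concordance, train the DRB345 copy-number
#' classifier and filter the ranked DRB345 calls, re-score, train the
#' composite selector and score the assembled composite, and summarize
#' per-cell ASE.  Stage outputs land in `outDir` together with a
#' machine-readable JSON manifest carrying the seed, the config hash and
#' headline metrics; any stage failure aborts with the stage named.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created if needed).
#' @param fieldLevels field levels to evaluate (default 1:3).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = simulationConfig(), outDir,
                        fieldLevels = 1:3) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    sim <- stage("simulate", simulateAll(config, dir = outDir))
    conc <- stage("concordance", {
        cc <- summarizeConcordance(sim$calls, sim$truth, fieldLevels)
        utils::write.table(cc, file.path(outDir, "concordance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cc
    })
    ent <- stage("entropy", {
        pr <- profileAlignment(sim$msa, window = 100L, locus = "synthetic")
        writeEntropyProfile(pr, file.path(outDir, "entropy.tsv"))
        pr
    })
    cnres <- stage("drb-cn", {
        feats <- computeRatioFeatures(sim$readCounts)
        model <- trainCopyNumberModel(feats, sim$copyNumbers,
                                      seed = config$seed + 10L)
        pred <- predictCopyNumbers(model, feats)
        utils::write.table(pred, file.path(outDir, "copy_number_pred.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ho <- pred$sample_id %in% model@holdout
        truthHo <- sim$copyNumbers[match(pred$sample_id[ho],
                                         sim$copyNumbers$sample_id), ]
        auc <- mean(vapply(.PARALOGS, function(p) {
            lab <- truthHo[[tolower(p)]]
            if (length(unique(lab)) < 2L) return(NA_real_)
            handTillAUC(attr(pred, "scores")[[p]][ho, , drop = FALSE], lab)
        }, numeric(1L)), na.rm = TRUE)
        simil <- copyNumberSimilarity(
            truthHo[, c("drb3", "drb4", "drb5")],
            pred[ho, c("drb3", "drb4", "drb5")])
        list(model = model, pred = pred, holdoutAUC = auc,
             meanSimilarity = mean(simil))
    })
    filt <- stage("drb-filter", {
        filtered <- filterGenotypeByCopyNumber(sim$calls, cnres$pred)
        writeGenotypeTable(filtered, file.path(outDir, "calls_filtered.tsv"))
        cc <- summarizeConcordance(filtered, sim$truth, fieldLevels)
        utils::write.table(cc, file.path(outDir, "concordance_filtered.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cc
    })
    comp <- stage("composite", {
        inst <- buildSelectorInstances(sim$calls, sim$truth, fieldLevels)
        sel <- trainSelector(inst, seed = config$seed + 20L)
        comps <- lapply(fieldLevels, function(f)
            assembleComposite(sim$calls, sel, f))
        ccs <- lapply(seq_along(fieldLevels), function(i) {
            cc <- summarizeConcordance(comps[[i]], sim$truth,
                                       fieldLevels[i])
            cc
        })
        cc <- do.call(rbind, ccs)
        utils::write.table(cc, file.path(outDir, "concordance_composite.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeGenotypeTable(comps[[1L]], file.path(outDir, "composite.tsv"))
        list(selector = sel, summary = cc)
    })
    ase <- stage("ase", {
        gs <- summarizeGroups(sim$cellCounts)
        utils::write.table(gs, file.path(outDir, "ase_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        gs
    })
    manifest <- list(
        package = as.character(utils::packageVersion("hlacomposite")),
        seed = config$seed,
        config_hash = rlang::hash(config),
        n_samples = config$nSamples,
        outputs = list.files(outDir),
        metrics = list(
            mean_accuracy_field2 = mean(
                conc$mean_accuracy[conc$field_level == 2L], na.rm = TRUE),
            drb_holdout_hand_till_auc = cnres$holdoutAUC,
            drb_mean_similarity = cnres$meanSimilarity,
            selector_holdout_auc = comp$selector@holdoutAUC,
            ase_summary_log_odds = stats::setNames(
                as.list(ase$summary_log_odds), ase$group)))
    manifest$manifest_hash <- rlang::hash(manifest)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
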