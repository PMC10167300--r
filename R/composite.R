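#' Composite-genotyper selector model
#'
#' A decision tree that, for a sample x locus x field slot, predicts which
#' upstream genotyper gives the most accurate call there, from which
#' genotypers produced a valid (non-empty) genotype plus the locus and
#' field level.  Assembling the selected genotypers' calls yields a
#' composite genotype that can beat every single tool.
#'
#' @slot fit list holding the fitted tree (see internals), its classes and
#'   hyperparameters.
#' @slot roster character vector of genotyper names the model knows.
#' @slot priority character vector: tie-break and fallback order.
#' @slot loci,fieldLevels feature vocabularies seen in training.
#' @slot cv data.frame of cross-validated accuracy over the cp grid.
#' @slot holdout character vector of holdout sample ids.
#' @slot holdoutAUC Hand & Till AUC on the holdout instances (`NA` if not
#'   computable).
#' @slot seed integer seed used for the split and folds.
#' @slot notes training warnings (e.g. single-label degenerate fit).
#' @export
setClass("SelectorModel",
    representation(fit = "list", roster = "character", priority = "character",
                   loci = "character", fieldLevels = "integer",
                   cv = "data.frame", holdout = "character",
                   holdoutAUC = "numeric", seed = "integer",
                   notes = "character"))

#' @describeIn SelectorModel concise display.
#' @param object a `SelectorModel`.
#' @export
setMethod("show", "SelectorModel", function(object) {
    cat(sprintf(
        "SelectorModel over {%s}: holdout Hand-Till AUC %.3f, %d holdout samples\n",
        paste(object@roster, collapse = ", "),
        object@holdoutAUC, length(object@holdout)))
    if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})

# fastest-first default priority for the commonly benchmarked tools;
# genotypers outside this list keep their order of appearance
.DEFAULT_PRIORITY <- c("arcasHLA", "OptiType", "PHLAT", "HLAminer")

.rosterPriority <- function(roster, priority = NULL) {
    if (is.null(priority))
        priority <- c(intersect(.DEFAULT_PRIORITY, roster),
                      setdiff(roster, .DEFAULT_PRIORITY))
    stopifnot(setequal(priority, roster))
    priority
}

#' Build selector training instances
#'
#' One instance per sample x locus x field level with at least one
#' available genotyper: the availability of a valid genotype from each
#' genotyper, and as label the genotyper with the highest locus accuracy
#' against the molecular truth there.  Accuracy ties are broken by the
#' fixed `priority` order.
#'
#' @param callset predictions, a [GenotypeCallset-class].
#' @param truth molecular genotypes, a [GenotypeCallset-class].
#' @param fieldLevels integer vector of field levels (default 1:3).
#' @param priority genotyper tie-break order; default arcasHLA > OptiType >
#'   PHLAT > HLAminer, then order of appearance.
#' @return data.frame with columns `sample_id`, `locus`, `field_level`,
#'   one logical `avail_<genotyper>` column per roster member, `label`,
#'   and `best_accuracy` (the label's accuracy, kept for oracle analyses).
#' @export
buildSelectorInstances <- function(callset, truth, fieldLevels = 1:3,
                                   priority = NULL) {
    stopifnot(is(callset, "GenotypeCallset"), is(truth, "GenotypeCallset"))
    pdf <- callTable(callset); tdf <- callTable(truth)
    roster <- unique(pdf$genotyper)
    priority <- .rosterPriority(roster, priority)
    samples <- intersect(unique(tdf$sample_id), unique(pdf$sample_id))
    if (!length(samples)) stop("no overlapping samples between callset and truth")
    tdf <- tdf[tdf$sample_id %in% samples & !is.na(tdf$allele1), , drop = FALSE]

    out <- list()
    for (f in fieldLevels) {
        truncMap <- .truncationMap(c(tdf$allele1, tdf$allele2,
                                     pdf$allele1, pdf$allele2), f)
        for (i in seq_len(nrow(tdf))) {
            s <- tdf$sample_id[i]; l <- tdf$locus[i]
            tAl <- truncMap[stats::na.omit(c(tdf$allele1[i], tdf$allele2[i]))]
            avail <- logical(length(priority)); names(avail) <- priority
            acc <- rep(NA_real_, length(priority)); names(acc) <- priority
            for (g in priority) {
                j <- which(pdf$genotyper == g & pdf$sample_id == s &
                           pdf$locus == l)
                pAl <- if (length(j))
                    truncMap[stats::na.omit(
                        c(pdf$allele1[j[1L]], pdf$allele2[j[1L]]))]
                else character(0L)
                avail[g] <- length(pAl) > 0L
                if (avail[g])
                    acc[g] <- locusAccuracy(.countsFromTruncated(pAl, tAl))
            }
            if (!any(avail)) next
            best <- priority[avail][which.max(acc[priority[avail]])]
            row <- data.frame(sample_id = s, locus = l, field_level = f,
                              label = best,
                              best_accuracy = max(acc[avail]))
            for (g in priority) row[[paste0("avail_", g)]] <- avail[[g]]
            out[[length(out) + 1L]] <- row
        }
    }
    if (!length(out)) stop("no selector instances could be built")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "priority") <- priority
    res
}

# one-hot design matrix for selector instances
.selectorDesign <- function(instances, loci, fieldLevels, roster) {
    n <- nrow(instances)
    cols <- c(paste0("locus_", loci), paste0("field_", fieldLevels),
              paste0("avail_", roster))
    x <- matrix(FALSE, n, length(cols), dimnames = list(NULL, cols))
    for (l in loci) x[, paste0("locus_", l)] <- instances$locus == l
    for (f in fieldLevels)
        x[, paste0("field_", f)] <- instances$field_level == f
    for (g in roster) {
        cn <- paste0("avail_", g)
        if (cn %in% names(instances)) x[, cn] <- instances[[cn]]
    }
    x
}

#' Train the composite-genotyper selector
#'
#' Fits the decision tree on a 70% sample split with the complexity
#' parameter chosen by cross-validated accuracy, and records the Hand &
#' Till multiclass AUC of the tree's class probabilities on the 30%
#' holdout instances.
#'
#' @param instances data.frame from [buildSelectorInstances()].
#' @param trainFraction fraction of samples in the training split
#'   (default 0.7; must be < 1).
#' @param cvFolds folds for the cp tuning (default 10).
#' @param cpGrid candidate complexity parameters.
#' @param maxdepth,minbucket tree growth limits (defaults 8 and 5).
#' @param seed integer seed for split and folds.
#' @return a [SelectorModel-class].
#' @export
trainSelector <- function(instances, trainFraction = 0.7, cvFolds = 10L,
                          cpGrid = c(0.02, 0.005, 0.001), maxdepth = 8L,
                          minbucket = 5L, seed = 1L) {
    stopifnot(trainFraction > 0)
    if (trainFraction >= 1)
        stop("trainFraction must be < 1: an empty holdout set cannot validate the model")
    priority <- attr(instances, "priority")
    if (is.null(priority))
        priority <- .rosterPriority(unique(instances$label))
    roster <- priority
    loci <- sort(unique(instances$locus))
    fieldLevels <- sort(unique(instances$field_level))
    seed <- as.integer(seed)

    ids <- sort(unique(instances$sample_id))
    set.seed(seed)
    trainIds <- sort(sample(ids, max(1L, floor(trainFraction * length(ids)))))
    holdout <- setdiff(ids, trainIds)
    tr <- instances[instances$sample_id %in% trainIds, , drop = FALSE]
    te <- instances[instances$sample_id %in% holdout, , drop = FALSE]

    notes <- character(0L)
    xtr <- .selectorDesign(tr, loci, fieldLevels, roster)
    ytr <- factor(tr$label, levels = roster)
    cvRec <- data.frame(cp = cpGrid, cv_accuracy = NA_real_)
    if (length(unique(tr$label)) < 2L) {
        notes <- c(notes, sprintf(
            "single label '%s' in training data: degenerate constant model",
            unique(tr$label)))
        cpBest <- cpGrid[1L]
    } else {
        folds <- .makeFolds(nrow(tr), cvFolds, seed + 101L)
        for (ci in seq_along(cpGrid)) {
            hits <- vapply(folds, function(teIdx) {
                trIdx <- setdiff(seq_len(nrow(tr)), teIdx)
                fit <- .fitTree(xtr[trIdx, , drop = FALSE],
                                droplevels(ytr[trIdx]),
                                maxdepth, minbucket, cpGrid[ci])
                pr <- .predictTreeProb(fit, xtr[teIdx, , drop = FALSE])
                mean(colnames(pr)[max.col(pr, "first")] ==
                     as.character(ytr[teIdx]))
            }, numeric(1L))
            cvRec$cv_accuracy[ci] <- mean(hits)
        }
        # ties prefer the larger cp (simpler tree): grid is ordered decreasing
        cpBest <- cpGrid[which.max(cvRec$cv_accuracy)]
    }
    fit <- .fitTree(xtr, ytr, maxdepth, minbucket, cpBest)

    hAUC <- NA_real_
    if (nrow(te) && length(unique(te$label)) >= 2L) {
        pr <- .predictTreeProb(fit, .selectorDesign(te, loci, fieldLevels,
                                                    roster))
        hAUC <- tryCatch(handTillAUC(pr, te$label), error = function(e) NA_real_)
    }
    new("SelectorModel", fit = fit, roster = roster, priority = priority,
        loci = loci, fieldLevels = as.integer(fieldLevels), cv = cvRec,
        holdout = holdout, holdoutAUC = hAUC, seed = seed, notes = notes)
}

#' Predict the best genotyper for each instance
#'
#' Tree class probabilities are masked to the genotypers actually available
#' at each instance (the composite must never emit a call from a genotyper
#' that produced none); among available genotypers the highest-probability
#' one wins, ties and all-zero masses falling back to the priority order.
#'
#' @param model a [SelectorModel-class].
#' @param instances data.frame with `locus`, `field_level` and
#'   `avail_<genotyper>` columns.
#' @return character vector of genotyper names (`NA` where none available).
#' @export
predictSelector <- function(model, instances) {
    stopifnot(is(model, "SelectorModel"))
    x <- .selectorDesign(instances, model@loci, model@fieldLevels,
                         model@roster)
    pr <- .predictTreeProb(model@fit, x)
    # classes absent from the fit get zero mass
    full <- matrix(0, nrow(pr), length(model@roster),
                   dimnames = list(NULL, model@roster))
    full[, colnames(pr)] <- pr
    out <- rep(NA_character_, nrow(x))
    for (i in seq_len(nrow(x))) {
        avail <- model@roster[vapply(model@roster, function(g) {
            cn <- paste0("avail_", g)
            cn %in% names(instances) && isTRUE(instances[[cn]][i])
        }, logical(1L))]
        if (!length(avail)) next
        p <- full[i, avail]
        # order candidates by probability, then priority, deterministically
        byPriority <- match(avail, model@priority)
        out[i] <- avail[order(-p, byPriority)][1L]
    }
    out
}

#' Assemble a composite genotype callset
#'
#' For every sample x locus slot at the given field level, the selector
#' picks the genotyper to trust; that genotyper's call, truncated to the
#' field level, becomes the composite call.  Slots where no genotyper made
#' a call stay empty.
#'
#' @param callset predictions from the roster genotypers.
#' @param model a trained [SelectorModel-class].
#' @param fieldLevel single field level to assemble at.
#' @param name genotyper name for the composite (default
#'   `composite(<initials>)`).
#' @return a [GenotypeCallset-class] containing the single composite
#'   genotyper.
#' @export
assembleComposite <- function(callset, model, fieldLevel,
                              name = NULL) {
    stopifnot(is(callset, "GenotypeCallset"), is(model, "SelectorModel"),
              length(fieldLevel) == 1L)
    pdf <- callTable(callset)
    roster <- model@roster
    if (!all(unique(pdf$genotyper) %in% roster))
        stop("callset contains genotypers outside the model roster")
    if (is.null(name))
        name <- sprintf("composite(%s)",
                        paste(substr(roster, 1L, 1L), collapse = ""))
    slots <- unique(pdf[, c("sample_id", "locus")])
    inst <- data.frame(sample_id = slots$sample_id, locus = slots$locus,
                       field_level = fieldLevel)
    for (g in roster) {
        key <- paste(pdf$sample_id, pdf$locus)[pdf$genotyper == g &
                                               !is.na(pdf$allele1)]
        inst[[paste0("avail_", g)]] <- paste(slots$sample_id, slots$locus) %in% key
    }
    pick <- predictSelector(model, inst)
    a1 <- rep(NA_character_, nrow(slots)); a2 <- a1
    for (i in seq_len(nrow(slots))) {
        if (is.na(pick[i])) next
        al <- .callAlleles(callset, slots$sample_id[i], pick[i],
                           slots$locus[i])
        al <- truncateAllele(al, fieldLevel)
        if (length(al) >= 1L) a1[i] <- al[1L]
        if (length(al) >= 2L) a2[i] <- al[2L]
    }
    GenotypeCallset(data.frame(
        sample_id = slots$sample_id, genotyper = name, locus = slots$locus,
        allele1 = a1, allele2 = a2), ranked = isRanked(callset))
}
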