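#' Count correct, incorrect and absent alleles for one locus
#'
#' Scores a predicted genotype against the molecular (ground-truth) genotype
#' of one locus by a maximum one-to-one matching of allele slots under
#' [allelesMatch()] at the requested field resolution.  Unmatched predicted
#' alleles are incorrect; unmatched truth slots are absent.  A homozygous
#' truth `{X, X}` against a single prediction `{X}` therefore scores one
#' correct and one absent allele: the matching is over allele slots, so two
#' truth copies need two predicted copies.
#'
#' @param truth character vector of ground-truth allele names (non-empty).
#' @param pred character vector of predicted allele names (may be empty).
#' @param fieldLevel field resolution at which alleles are compared.
#' @return named integer vector `c(n_correct, n_incorrect, n_absent)`.
#' @examples
#' countCorrect(c("A*02:01", "A*03:01"), c("A*03:01", "A*02:05"), 2)
#' @export
countCorrect <- function(truth, pred, fieldLevel) {
    if (!length(truth))
        stop("ground-truth genotype must contain at least one allele")
    tA <- parseAllele(truth)
    loci <- unique(alleleLocus(tA))
    if (length(pred)) {
        pA <- parseAllele(pred)
        loci <- unique(c(loci, alleleLocus(pA)))
    }
    if (length(loci) != 1L)
        stop(sprintf("locus mismatch between truth and prediction: %s",
                     paste(loci, collapse = ", ")))
    m <- 0L
    if (length(pred)) {
        hit <- outer(seq_along(pred), seq_along(truth),
                     function(i, j) allelesMatch(pred[i], truth[j], fieldLevel))
        hit <- matrix(hit, nrow = length(pred))
        m <- .maxBipartiteMatch(hit)
    }
    c(n_correct = m,
      n_incorrect = length(pred) - m,
      n_absent = length(truth) - m)
}

# maximum bipartite matching size by augmenting paths; rows = predictions
.maxBipartiteMatch <- function(hit) {
    nr <- nrow(hit); nc <- ncol(hit)
    if (!nr || !nc) return(0L)
    env <- new.env()
    env$matchCol <- rep(0L, nc)
    tryAugment <- function(r) {
        for (c in seq_len(nc)) {
            if (hit[r, c] && !env$seen[c]) {
                env$seen[c] <- TRUE
                if (env$matchCol[c] == 0L || tryAugment(env$matchCol[c])) {
                    env$matchCol[c] <- r
                    return(TRUE)
                }
            }
        }
        FALSE
    }
    m <- 0L
    for (r in seq_len(nr)) {
        env$seen <- rep(FALSE, nc)
        if (tryAugment(r)) m <- m + 1L
    }
    m
}

#' Genotyping success for one locus
#'
#' Success is the proportion of predicted alleles that are correct,
#' `correct / (correct + incorrect)`, and ignores missing predictions: a
#' locus where the genotyper produced no alleles is undefined (`NA`), not
#' zero, and is excluded from averages.
#'
#' @param counts named vector as returned by [countCorrect()].
#' @return fraction in \[0, 1\], or `NA` when nothing was predicted.
#' @export
locusSuccess <- function(counts) {
    denom <- counts[["n_correct"]] + counts[["n_incorrect"]]
    if (denom == 0L) NA_real_ else counts[["n_correct"]] / denom
}

#' Genotyping accuracy for one locus
#'
#' Accuracy scores the prediction over all allele slots of the gold
#' standard, penalizing failed predictions through the absent term
#' (analogous to a Bray-Curtis similarity between the allele multisets).
#' The denominator counts genotype slots: an unmatched prediction occupies
#' the slot of an unmatched truth allele, so incorrect and absent overlap
#' rather than add, giving `correct / (correct + max(incorrect, absent))` =
#' `correct / max(n_pred, n_truth)`.  A diploid locus therefore takes only
#' the values 0, 0.5 or 1 (0, 1 or 2 of the 2 possible alleles correct):
#' one right and one wrong allele scores 0.5, exactly as one right and one
#' missing allele does.
#'
#' @param counts named vector as returned by [countCorrect()].
#' @return fraction in \[0, 1\].
#' @export
locusAccuracy <- function(counts) {
    counts[["n_correct"]] /
        (counts[["n_correct"]] + max(counts[["n_incorrect"]],
                                     counts[["n_absent"]]))
}

#' Agreement between two predicted genotypes
#'
#' Agreement is accuracy with the second prediction playing the truth role:
#' a "correct" allele is one on which the two predictions are identical at
#' the chosen field level.  Symmetric when both calls have the same number
#' of alleles.
#'
#' @param pred1,pred2 character vectors of allele names for one locus.
#' @param fieldLevel field resolution.
#' @return fraction in \[0, 1\]; `NA` when both calls are empty.
#' @export
genotypeAgreement <- function(pred1, pred2, fieldLevel) {
    if (!length(pred1) && !length(pred2)) return(NA_real_)
    if (!length(pred2)) {              # nothing to agree with: all incorrect
        return(0)
    }
    locusAccuracy(countCorrect(pred2, pred1, fieldLevel))
}

#' Expected agreement of two independent genotypers
#'
#' Under independent errors the expected agreement of two genotypers is the
#' product of their accuracies against the shared ground truth.
#'
#' @param acc1,acc2 accuracies in \[0, 1\].
#' @return `acc1 * acc2`.
#' @export
expectedAgreement <- function(acc1, acc2) {
    stopifnot(all(acc1 >= 0 & acc1 <= 1, na.rm = TRUE),
              all(acc2 >= 0 & acc2 <= 1, na.rm = TRUE))
    acc1 * acc2
}

# fast path used by summarizeConcordance: counts from already-truncated
# canonical names, where maximum matching reduces to multiset intersection
.countsFromTruncated <- function(pred, truth) {
    m <- 0L
    if (length(pred)) {
        tt <- table(truth); tp <- table(pred)
        shared <- intersect(names(tt), names(tp))
        m <- sum(pmin(tt[shared], tp[shared]))
    }
    c(n_correct = m, n_incorrect = length(pred) - m,
      n_absent = length(truth) - m)
}

#' Summarize concordance of a callset against molecular genotypes
#'
#' Computes per-sample success and accuracy for every genotyper x locus x
#' field level and averages over samples.  Loci that a genotyper never
#' assesses (no call rows for the locus in any sample) are reported as
#' not-assessed (`assessed = FALSE`) with `NA` means by default, mirroring
#' empty heatmap tiles rather than zero accuracy; set
#' `missingLocus = "zero"` to score them as complete failures instead.
#'
#' @param callset a [GenotypeCallset-class] of predictions.
#' @param truth a [GenotypeCallset-class] holding the molecular genotypes
#'   (a single genotyper).
#' @param fieldLevels integer vector of field resolutions to evaluate.
#' @param missingLocus `"exclude"` (default) or `"zero"`: treatment of loci
#'   outside a genotyper's repertoire.
#' @param emptyTruth `"skip"` (default) drops truth rows with no alleles;
#'   `"score"` keeps them and scores a prediction there as accuracy 1 when
#'   it is also empty and 0 otherwise.  The latter is how zero-copy DRB345
#'   paralogs are assessed, where calling nothing is the correct genotype
#'   and any call is a false positive.
#' @return data.frame with columns `genotyper`, `locus`, `field_level`,
#'   `n_samples`, `mean_success`, `mean_accuracy`, `assessed`.
#' @export
summarizeConcordance <- function(callset, truth, fieldLevels = 1:3,
                                 missingLocus = c("exclude", "zero"),
                                 emptyTruth = c("skip", "score")) {
    missingLocus <- match.arg(missingLocus)
    emptyTruth <- match.arg(emptyTruth)
    stopifnot(is(callset, "GenotypeCallset"), is(truth, "GenotypeCallset"))
    tdf <- callTable(truth); pdf <- callTable(callset)
    if (length(unique(tdf$genotyper)) > 1L)
        stop("truth callset must contain a single genotyper")
    samples <- intersect(unique(tdf$sample_id), unique(pdf$sample_id))
    if (!length(samples)) stop("no overlapping samples between callset and truth")
    tdf <- tdf[tdf$sample_id %in% samples, , drop = FALSE]
    if (emptyTruth == "skip")
        tdf <- tdf[!is.na(tdf$allele1), , drop = FALSE]
    pdf <- pdf[pdf$sample_id %in% samples, , drop = FALSE]
    genotypers <- unique(pdf$genotyper)
    loci <- unique(tdf$locus)
    # loci with at least one call row (even an empty one) define the repertoire
    assessedMap <- unique(pdf[, c("genotyper", "locus")])

    out <- list()
    for (f in fieldLevels) {
        truncMap <- .truncationMap(c(tdf$allele1, tdf$allele2,
                                     pdf$allele1, pdf$allele2), f)
        for (g in genotypers) {
            pg <- pdf[pdf$genotyper == g, , drop = FALSE]
            for (l in loci) {
                tl <- tdf[tdf$locus == l, , drop = FALSE]
                if (!nrow(tl)) next
                assessed <- any(assessedMap$genotyper == g &
                                assessedMap$locus == l)
                if (!assessed) {
                    acc <- if (missingLocus == "zero") 0 else NA_real_
                    out[[length(out) + 1L]] <- data.frame(
                        genotyper = g, locus = l, field_level = f,
                        n_samples = nrow(tl), mean_success = NA_real_,
                        mean_accuracy = acc, assessed = FALSE)
                    next
                }
                pl <- pg[pg$locus == l, , drop = FALSE]
                succ <- acc <- numeric(nrow(tl))
                for (i in seq_len(nrow(tl))) {
                    s <- tl$sample_id[i]
                    tAl <- truncMap[stats::na.omit(
                        c(tl$allele1[i], tl$allele2[i]))]
                    j <- which(pl$sample_id == s)
                    pAl <- if (length(j))
                        truncMap[stats::na.omit(
                            c(pl$allele1[j[1L]], pl$allele2[j[1L]]))]
                    else character(0L)
                    cnt <- .countsFromTruncated(pAl, tAl)
                    succ[i] <- locusSuccess(cnt)
                    acc[i] <- if (!length(tAl) && !length(pAl)) 1
                              else locusAccuracy(cnt)
                }
                out[[length(out) + 1L]] <- data.frame(
                    genotyper = g, locus = l, field_level = f,
                    n_samples = nrow(tl),
                    mean_success = if (all(is.na(succ))) NA_real_
                                   else mean(succ, na.rm = TRUE),
                    mean_accuracy = mean(acc), assessed = TRUE)
            }
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# named lookup: allele string -> canonical truncated form at field level f
.truncationMap <- function(alleles, fieldLevel) {
    u <- unique(stats::na.omit(alleles))
    if (!length(u)) return(stats::setNames(character(0L), character(0L)))
    stats::setNames(truncateAllele(u, fieldLevel), u)
}
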