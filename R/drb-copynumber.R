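.PARALOGS <- c("DRB3", "DRB4", "DRB5")

#' Paralog/DRB1 read-ratio features
#'
#' HLA-DRB3/4/5 are paralogous genes carried by 0-2 haplotypes per diploid
#' individual, in linkage with particular DRB1 allele groups.  Because a
#' haplotype carries at most one of them, the number of reads mapping to a
#' paralog scales with its copy number, and the ratio to the always-present
#' DRB1 read count removes depth differences between samples.  A sample
#' with zero DRB1 reads is flagged un-callable rather than patched with a
#' pseudocount.
#'
#' @param readCounts data.frame with columns `sample_id`, `locus`, `reads`
#'   (integer mapped-read counts); missing paralog rows count as 0 reads.
#' @return data.frame with columns `sample_id`, `ratio_drb3`, `ratio_drb4`,
#'   `ratio_drb5`, `callable`.
#' @export
computeRatioFeatures <- function(readCounts) {
    stopifnot(all(c("sample_id", "locus", "reads") %in% names(readCounts)))
    samples <- unique(readCounts$sample_id)
    get <- function(s, l) {
        r <- readCounts$reads[readCounts$sample_id == s & readCounts$locus == l]
        if (!length(r)) 0 else sum(r)
    }
    res <- lapply(samples, function(s) {
        drb1 <- get(s, "DRB1")
        if (drb1 <= 0)
            return(data.frame(sample_id = s, ratio_drb3 = NA_real_,
                              ratio_drb4 = NA_real_, ratio_drb5 = NA_real_,
                              callable = FALSE))
        data.frame(sample_id = s,
                   ratio_drb3 = get(s, "DRB3") / drb1,
                   ratio_drb4 = get(s, "DRB4") / drb1,
                   ratio_drb5 = get(s, "DRB5") / drb1,
                   callable = TRUE)
    })
    do.call(rbind, res)
}

#' Fitted DRB345 copy-number classifier
#'
#' One k-nearest-neighbour model per paralog (default) on the single
#' paralog/DRB1 ratio feature, or one joint 3-feature model.  The stored
#' state is the training feature/label set plus the tuned `k`.
#'
#' @slot mode `"per-paralog"` or `"joint"`.
#' @slot train list of per-paralog training stores (features, labels, k).
#' @slot k named integer vector of tuned neighbourhood sizes.
#' @slot cv data.frame of cross-validation accuracies over the k grid.
#' @slot holdout character vector of holdout sample ids.
#' @slot seed integer seed used for the split and folds.
#' @slot notes character vector of training warnings (e.g. absent classes).
#' @export
setClass("CopyNumberModel",
    representation(mode = "character", train = "list", k = "integer",
                   cv = "data.frame", holdout = "character", seed = "integer",
                   notes = "character"))

setValidity("CopyNumberModel", function(object) {
    if (!object@mode %in% c("per-paralog", "joint"))
        return("mode must be 'per-paralog' or 'joint'")
    if (any(object@k < 1L)) return("k must be positive")
    TRUE
})

#' @describeIn CopyNumberModel concise display.
#' @param object a `CopyNumberModel`.
#' @export
setMethod("show", "CopyNumberModel", function(object) {
    cat(sprintf("CopyNumberModel (%s): k = {%s}, %d training samples, %d holdout\n",
        object@mode, paste(names(object@k), object@k, sep = "=", collapse = ", "),
        nrow(object@train[[1L]]$features), length(object@holdout)))
    if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})

# kNN vote fractions over classes; x: train matrix, y: train labels (factor),
# q: query matrix. Distance: absolute difference (1-D) / Euclidean (joint).
# Vote ties go to the LOWER copy number (conservative against spurious
# paralog calls).
.knnScores <- function(x, y, q, k) {
    x <- as.matrix(x); q <- as.matrix(q)
    classes <- levels(y)
    scores <- matrix(0, nrow(q), length(classes),
                     dimnames = list(NULL, classes))
    k <- min(k, nrow(x))
    for (i in seq_len(nrow(q))) {
        d <- sqrt(colSums((t(x) - q[i, ])^2))
        ord <- order(d)
        kd <- d[ord[k]]
        nb <- which(d <= kd + 1e-12)      # include distance ties
        v <- table(y[nb]) / length(nb)
        scores[i, names(v)] <- as.numeric(v)
    }
    scores
}

.knnPredict <- function(scores) {
    classes <- as.integer(colnames(scores))
    apply(scores, 1L, function(s) classes[which(s == max(s))][1L])
}

#' Train the DRB345 copy-number classifier
#'
#' Splits samples 70/30 into training and holdout sets, tunes `k` by
#' cross-validated accuracy over `kGrid` within the training set, and
#' stores one kNN per paralog (or one joint model).  The ground truth is
#' the molecular copy-number vector per sample.
#'
#' @param features data.frame from [computeRatioFeatures()].
#' @param truth data.frame with columns `sample_id`, `drb3`, `drb4`, `drb5`
#'   (each in 0..2).
#' @param trainFraction fraction of samples used for training (default 0.7;
#'   must leave a non-empty holdout).
#' @param cvFolds number of cross-validation folds for tuning (default 10).
#' @param kGrid candidate neighbourhood sizes (default 3, 5, 7, 9, 11).
#' @param mode `"per-paralog"` (default; one 1-D model per paralog) or
#'   `"joint"` (one 3-D model predicting each paralog from all ratios).
#' @param seed integer seed for the split and fold assignment.
#' @return a [CopyNumberModel-class].
#' @export
trainCopyNumberModel <- function(features, truth, trainFraction = 0.7,
                                 cvFolds = 10L, kGrid = c(3L, 5L, 7L, 9L, 11L),
                                 mode = c("per-paralog", "joint"),
                                 seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(trainFraction > 0)
    if (trainFraction >= 1)
        stop("trainFraction must be < 1: an empty holdout set cannot validate the model")
    df <- merge(features[features$callable, , drop = FALSE], truth,
                by = "sample_id")
    if (!nrow(df)) stop("no callable samples shared between features and truth")
    seed <- as.integer(seed)
    ids <- sort(df$sample_id)
    set.seed(seed)
    nTrain <- max(1L, floor(trainFraction * length(ids)))
    trainIds <- sort(sample(ids, nTrain))
    holdout <- setdiff(ids, trainIds)
    tr <- df[df$sample_id %in% trainIds, , drop = FALSE]

    ratioCol <- function(p) paste0("ratio_", tolower(p))
    cnCol <- function(p) tolower(p)
    notes <- character(0L)
    cvRec <- list(); kSel <- integer(0L); store <- list()
    for (p in .PARALOGS) {
        y <- factor(tr[[cnCol(p)]], levels = 0:2)
        absent <- setdiff(0:2, unique(tr[[cnCol(p)]]))
        if (length(absent))
            notes <- c(notes, sprintf(
                "%s: copy-number class(es) %s absent from training data",
                p, paste(absent, collapse = ",")))
        x <- if (mode == "per-paralog") tr[, ratioCol(p), drop = FALSE]
             else tr[, ratioCol(.PARALOGS), drop = FALSE]
        folds <- .makeFolds(nrow(tr), cvFolds, seed + match(p, .PARALOGS))
        accs <- vapply(kGrid, function(k) {
            hits <- vapply(seq_along(folds), function(fi) {
                te <- folds[[fi]]; trn <- setdiff(seq_len(nrow(tr)), te)
                if (!length(te) || !length(trn)) return(NA_real_)
                sc <- .knnScores(x[trn, , drop = FALSE], droplevels(y[trn]),
                                 x[te, , drop = FALSE], k)
                # align score columns back onto the full class set
                full <- matrix(0, length(te), 3L,
                               dimnames = list(NULL, as.character(0:2)))
                full[, colnames(sc)] <- sc
                mean(.knnPredict(full) == as.integer(as.character(y[te])))
            }, numeric(1L))
            mean(hits, na.rm = TRUE)
        }, numeric(1L))
        kBest <- kGrid[which.max(accs)]   # ties -> smallest k in grid order
        kSel[p] <- as.integer(kBest)
        cvRec[[p]] <- data.frame(paralog = p, k = kGrid, cv_accuracy = accs)
        store[[p]] <- list(features = x, labels = y, k = as.integer(kBest))
    }
    new("CopyNumberModel", mode = mode, train = store, k = kSel,
        cv = do.call(rbind, cvRec), holdout = holdout, seed = seed,
        notes = notes)
}

.makeFolds <- function(n, folds, seed) {
    set.seed(seed)
    folds <- max(2L, min(folds, n))
    split(sample(seq_len(n)), rep_len(seq_len(folds), n))
}

#' Predict DRB345 copy numbers
#'
#' Applies the fitted kNN to new ratio features.  Vote ties are broken
#' toward the lower copy number.  Predicted vectors whose copies sum to
#' more than 2 are biologically impossible for a diploid genome and are
#' reported as-is but flagged.
#'
#' @param model a [CopyNumberModel-class].
#' @param features data.frame from [computeRatioFeatures()]; un-callable
#'   samples receive no prediction.
#' @return data.frame with columns `sample_id`, `drb3`, `drb4`, `drb5`,
#'   `valid` (copy sum <= 2); per-paralog vote-score matrices are attached
#'   as attribute `"scores"` (a named list of n x 3 matrices).
#' @export
predictCopyNumbers <- function(model, features) {
    stopifnot(is(model, "CopyNumberModel"))
    feat <- features[features$callable, , drop = FALSE]
    if (!nrow(feat))
        stop("no callable samples to predict")
    pred <- data.frame(sample_id = feat$sample_id)
    scores <- list()
    for (p in .PARALOGS) {
        st <- model@train[[p]]
        q <- if (model@mode == "per-paralog")
            feat[, paste0("ratio_", tolower(p)), drop = FALSE]
        else feat[, paste0("ratio_", tolower(.PARALOGS)), drop = FALSE]
        sc <- .knnScores(st$features, st$labels, q, st$k)
        full <- matrix(0, nrow(q), 3L,
                       dimnames = list(feat$sample_id, as.character(0:2)))
        full[, colnames(sc)] <- sc
        scores[[p]] <- full
        pred[[tolower(p)]] <- .knnPredict(full)
    }
    pred$valid <- (pred$drb3 + pred$drb4 + pred$drb5) <= 2L
    attr(pred, "scores") <- scores
    pred
}

#' Hand & Till multiclass AUC
#'
#' The multiclass generalization of the AUROC: the unweighted mean over all
#' unordered class pairs (i, j) of \eqn{\hat{A}(i,j) = (A(i|j) + A(j|i))/2},
#' where \eqn{A(i|j)} is the probability that a random class-i sample gets a
#' higher class-i score than a random class-j sample (ties count 1/2),
#' computed on samples of classes i and j only.
#'
#' @param scores numeric matrix of class scores, one column per class
#'   (column names are the class labels), one row per sample.
#' @param labels vector of true class labels.
#' @return AUC in \[0, 1\].
#' @export
handTillAUC <- function(scores, labels) {
    scores <- as.matrix(scores)
    labels <- as.character(labels)
    if (is.null(colnames(scores)))
        stop("scores must carry class labels as column names")
    present <- intersect(colnames(scores), unique(labels))
    if (length(present) < 2L)
        stop("Hand & Till AUC needs at least 2 classes present")
    pairAUC <- function(ci, cj) {
        # A(i|j) from the class-i score column, restricted to classes i, j
        ii <- labels == ci; jj <- labels == cj
        s <- scores[ii | jj, ci]
        isI <- labels[ii | jj] == ci
        r <- rank(s)                  # midranks handle ties as 1/2
        ni <- sum(isI); nj <- sum(!isI)
        (sum(r[isI]) - ni * (ni + 1) / 2) / (ni * nj)
    }
    tot <- 0; np <- 0L
    for (a in seq_along(present)) for (b in seq_along(present)) {
        if (a >= b) next
        ci <- present[a]; cj <- present[b]
        tot <- tot + (pairAUC(ci, cj) + pairAUC(cj, ci)) / 2
        np <- np + 1L
    }
    tot / np
}

#' Copy-number vector similarity
#'
#' One minus the Manhattan distance between two {DRB3, DRB4, DRB5}
#' copy-number vectors, standardized to the maximum possible distance of 6
#' (two alleles differing at each of the three loci): 1 is complete
#' similarity, 0 complete dissimilarity.
#'
#' @param truth,pred numeric vectors of length 3 (or data.frames with
#'   columns `drb3`, `drb4`, `drb5`), entries in 0..2.
#' @return similarity in \[0, 1\] (vectorized over data.frame rows).
#' @export
copyNumberSimilarity <- function(truth, pred) {
    asMat <- function(v) {
        if (is.data.frame(v)) as.matrix(v[, c("drb3", "drb4", "drb5")])
        else matrix(v, ncol = 3L)
    }
    a <- asMat(truth); b <- asMat(pred)
    stopifnot(all(a %in% 0:2), all(b %in% 0:2))
    1 - rowSums(abs(a - b)) / 6
}

#' Filter DRB345 genotype calls to the predicted copy number
#'
#' Upstream genotypers frequently call HLA-DRB3/4/5 alleles in samples that
#' carry no copy of the paralog.  Given predicted copy numbers, this keeps
#' only the top n ranked alleles per paralog (n = predicted copies); n = 0
#' empties the call.  Non-DRB345 loci pass through untouched.
#'
#' @param callset a [GenotypeCallset-class]; must be rank-ordered
#'   (`isRanked(callset)`) whenever filtering would have to drop an allele.
#' @param copyNumbers data.frame with columns `sample_id`, `drb3`, `drb4`,
#'   `drb5` (e.g. from [predictCopyNumbers()]).
#' @return a filtered [GenotypeCallset-class].
#' @export
filterGenotypeByCopyNumber <- function(callset, copyNumbers) {
    stopifnot(is(callset, "GenotypeCallset"))
    df <- callTable(callset)
    cn <- copyNumbers
    for (i in which(df$locus %in% .PARALOGS)) {
        j <- which(cn$sample_id == df$sample_id[i])
        if (!length(j)) next
        n <- cn[[tolower(df$locus[i])]][j[1L]]
        nCalls <- sum(!is.na(c(df$allele1[i], df$allele2[i])))
        if (nCalls > n) {
            if (!isRanked(callset))
                stop(paste("copy-number filtering needs a ranked callset:",
                           "supply the upstream genotyper's allele ordering"))
            if (n < 2L) df$allele2[i] <- NA_character_
            if (n < 1L) df$allele1[i] <- NA_character_
        }
    }
    GenotypeCallset(df, ranked = isRanked(callset))
}
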