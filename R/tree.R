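# Minimal CART classifier on binary (one-hot) features with gini impurity.
# Grown greedily; a split must leave >= minbucket rows in each child and
# reduce the root-normalized gini by at least cp. Trees are plain nested
# lists so a fitted model serializes as JSON.

.gini <- function(y) {
    p <- tabulate(y, nbins = nlevels(y)) / length(y)
    1 - sum(p^2)
}

.leaf <- function(y) {
    prob <- tabulate(y, nbins = nlevels(y)) / length(y)
    names(prob) <- levels(y)
    list(leaf = TRUE, prob = prob, n = length(y))
}

.growTree <- function(x, y, depth, maxdepth, minbucket, cp, rootImp) {
    n <- length(y)
    if (depth >= maxdepth || n < 2L * minbucket || length(unique(y)) < 2L)
        return(.leaf(y))
    imp <- .gini(y)
    best <- NULL; bestGain <- 0
    for (j in seq_len(ncol(x))) {
        left <- x[, j]
        nl <- sum(left); nr <- n - nl
        if (nl < minbucket || nr < minbucket) next
        gain <- imp - (nl * .gini(y[left]) + nr * .gini(y[!left])) / n
        if (gain > bestGain + 1e-12) { bestGain <- gain; best <- j }
    }
    # gain is normalized by the root impurity so cp has an rpart-like scale
    if (is.null(best) || bestGain / max(rootImp, 1e-12) < cp)
        return(.leaf(y))
    left <- x[, best]
    list(leaf = FALSE, feature = colnames(x)[best], n = n,
        yes = .growTree(x[left, , drop = FALSE], y[left], depth + 1L,
                        maxdepth, minbucket, cp, rootImp),
        no = .growTree(x[!left, , drop = FALSE], y[!left], depth + 1L,
                       maxdepth, minbucket, cp, rootImp))
}

.fitTree <- function(x, y, maxdepth = 8L, minbucket = 5L, cp = 0.001) {
    stopifnot(is.matrix(x) || is.data.frame(x))
    x <- as.matrix(x) > 0
    y <- droplevels(as.factor(y))
    tree <- .growTree(x, y, 0L, maxdepth, minbucket, cp, .gini(y))
    list(tree = tree, classes = levels(y),
         hyper = list(maxdepth = maxdepth, minbucket = minbucket, cp = cp))
}

.predictTreeProb <- function(fit, x) {
    x <- as.matrix(x) > 0
    out <- matrix(0, nrow(x), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
    for (i in seq_len(nrow(x))) {
        node <- fit$tree
        while (!node$leaf)
            node <- if (x[i, node$feature]) node$yes else node$no
        out[i, ] <- node$prob
    }
    out
}
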