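# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# exhaustive-assignment oracle for allele-slot matching: the maximum number
# of one-to-one (prediction, truth) pairs matching at the field level,
# found by enumerating every injective assignment
enumMatchCounts <- function(truth, pred, fieldLevel) {
    match1 <- function(p, t) {
        tp <- strsplit(sub("^[^*]+\\*", "", p), ":")[[1]]
        tt <- strsplit(sub("^[^*]+\\*", "", t), ":")[[1]]
        lp <- sub("\\*.*", "", p); lt <- sub("\\*.*", "", t)
        f <- fieldLevel
        identical(lp, lt) &&
            identical(tp[seq_len(min(f, length(tp)))],
                      tt[seq_len(min(f, length(tt)))]) &&
            (min(f, length(tp)) == min(f, length(tt)))
    }
    np <- length(pred); nt <- length(truth)
    best <- 0L
    if (np && nt) {
        k <- min(np, nt)
        predIdx <- seq_len(np); truthIdx <- seq_len(nt)
        # enumerate ordered selections of k truth slots for the first k preds
        perms <- function(v, k) {
            if (k == 0L) return(list(integer(0)))
            out <- list()
            for (i in seq_along(v))
                for (rest in perms(v[-i], k - 1L))
                    out[[length(out) + 1L]] <- c(v[i], rest)
            out
        }
        for (ps in perms(predIdx, k)) for (ts in perms(truthIdx, k)) {
            hits <- sum(mapply(function(pi, ti)
                match1(pred[pi], truth[ti]), ps, ts))
            best <- max(best, hits)
        }
    }
    c(n_correct = best, n_incorrect = np - best, n_absent = nt - best)
}

# brute-force Hand & Till AUC: double loop over sample pairs, ties = 1/2
bruteHandTill <- function(scores, labels) {
    labels <- as.character(labels)
    cls <- intersect(colnames(scores), unique(labels))
    aij <- function(ci, cj) {
        si <- scores[labels == ci, ci]; sj <- scores[labels == cj, ci]
        tot <- 0
        for (a in si) for (b in sj)
            tot <- tot + (a > b) + 0.5 * (a == b)
        tot / (length(si) * length(sj))
    }
    vals <- c()
    for (x in seq_along(cls)) for (y in seq_along(cls)) {
        if (x >= y) next
        vals <- c(vals, (aij(cls[x], cls[y]) + aij(cls[y], cls[x])) / 2)
    }
    mean(vals)
}

# build a GenotypeCallset from a compact list description:
# list("S1|g|A" = c("A*01:01","A*02:01"), ...)
makeCallset <- function(spec, ranked = FALSE) {
    rows <- lapply(names(spec), function(k) {
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        al <- spec[[k]]
        data.frame(sample_id = parts[1], genotyper = parts[2],
                   locus = parts[3],
                   allele1 = if (length(al) >= 1) al[1] else NA_character_,
                   allele2 = if (length(al) >= 2) al[2] else NA_character_)
    })
    GenotypeCallset(do.call(rbind, rows), ranked = ranked)
}

# mean accuracy across loci for one genotyper from a concordance summary
meanAcc <- function(summary, genotyper, field) {
    s <- summary[summary$genotyper == genotyper &
                 summary$field_level == field, ]
    mean(s$mean_accuracy, na.rm = TRUE)
}
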