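#' Per-cell allele-specific expression log-odds
#'
#' For one cell with reads `a` and `b` on the two alleles of a locus, the
#' expected counts under balanced expression put half of the total on each
#' allele.  The odds ratio of observed against expected counts, with the
#' higher-expressed allele as reference, reduces to `a/b` (the equal
#' expected cells cancel); its log and the standard 2x2 log-odds variance
#' `1/a + 1/b + 1/e + 1/e` (e = total/2) quantify per-cell imbalance and
#' its sampling uncertainty.  When any of the four table cells is zero, the
#' Haldane-Anscombe continuity increment is added to all four cells first.
#'
#' @param count1,count2 nonnegative integer read counts for the two alleles
#'   (vectorized).
#' @param continuity increment added to all four table cells when any cell
#'   is zero (default 0.5).
#' @param reference `"dominant"` (default; per-cell higher-expressed allele,
#'   log-odds always >= 0) or `"allele1"` (signed log-odds relative to the
#'   first allele, used when a common reference is imposed across cells).
#' @return data.frame with columns `log_odds`, `variance`,
#'   `reference_allele` (1 or 2), `total`.
#' @examples
#' cellLogOdds(6, 2)   # log(3), variance 1/6 + 1/2 + 1/4 + 1/4
#' @export
cellLogOdds <- function(count1, count2, continuity = 0.5,
                        reference = c("dominant", "allele1")) {
    reference <- match.arg(reference)
    stopifnot(length(count1) == length(count2),
              all(count1 >= 0), all(count2 >= 0))
    total <- count1 + count2
    if (any(total < 1))
        stop("cells with zero total reads must be excluded before scoring")
    if (reference == "dominant") {
        a <- pmax(count1, count2); b <- pmin(count1, count2)
        ref <- ifelse(count1 >= count2, 1L, 2L)
    } else {
        a <- count1; b <- count2
        ref <- rep(1L, length(count1))
    }
    e <- total / 2
    zero <- a == 0 | b == 0 | e == 0
    a <- a + ifelse(zero, continuity, 0)
    b <- b + ifelse(zero, continuity, 0)
    e1 <- e + ifelse(zero, continuity, 0)
    e2 <- e1
    data.frame(log_odds = log((a * e2) / (b * e1)),
               variance = 1 / a + 1 / b + 1 / e1 + 1 / e2,
               reference_allele = ref, total = total)
}

#' Random-effects pooling of per-cell effects (DerSimonian-Laird)
#'
#' Pools per-cell log-odds weighted by inverse variance, with the
#' between-cell heterogeneity tau2 estimated by the method of moments:
#' fixed weights `w = 1/v` give the fixed-effect mean and Cochran's Q;
#' `tau2 = max(0, (Q - (n-1)) / (sum(w) - sum(w^2)/sum(w)))`; random
#' weights `1/(v + tau2)` then give the summary effect and its standard
#' error `1/sqrt(sum(w*))`.  Low-count cells carry large variances and are
#' automatically down-weighted, which is the point of pooling on the
#' log-odds scale rather than averaging raw ratios.
#'
#' @param logOdds numeric vector of per-cell log-odds.
#' @param variance numeric vector of their within-cell variances.
#' @return list with `summary_log_odds`, `standard_error`, `tau2`,
#'   `n_cells`, and `Q`.
#' @export
poolRandomEffects <- function(logOdds, variance) {
    stopifnot(length(logOdds) == length(variance), all(variance > 0))
    n <- length(logOdds)
    if (!n) stop("cannot pool an empty set of effects")
    w <- 1 / variance
    yFE <- sum(w * logOdds) / sum(w)
    Q <- sum(w * (logOdds - yFE)^2)
    tau2 <- if (n > 1L)
        max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
    else 0
    ws <- 1 / (variance + tau2)
    list(summary_log_odds = sum(ws * logOdds) / sum(ws),
         standard_error = 1 / sqrt(sum(ws)),
         tau2 = tau2, n_cells = n, Q = Q)
}

#' Per-group ASE summaries
#'
#' Scores every cell with [cellLogOdds()] and pools each group (e.g. cell
#' type) with [poolRandomEffects()].  By default the reference allele is
#' fixed per group to the allele with the larger total count across the
#' group's cells, so cells favoring the minor allele contribute negative
#' log-odds and the pooled effect keeps its biological direction; with
#' `reference = "dominant"` every cell uses its own higher-expressed allele
#' and the summary is a pure imbalance magnitude.
#'
#' @param cells data.frame with columns `cell_id`, `count_allele1`,
#'   `count_allele2` and optionally `group` (one summary per group; a
#'   single group is assumed when absent).  Cells with zero total reads are
#'   dropped.
#' @param reference `"group"` (default) or `"dominant"`.
#' @param continuity continuity increment, see [cellLogOdds()].
#' @return data.frame with one row per group: `group`, `summary_log_odds`,
#'   `standard_error`, `tau2`, `n_cells`, `reference_allele`.
#' @export
summarizeGroups <- function(cells, reference = c("group", "dominant"),
                            continuity = 0.5) {
    reference <- match.arg(reference)
    stopifnot(all(c("count_allele1", "count_allele2") %in% names(cells)))
    if (!"group" %in% names(cells)) cells$group <- "all"
    cells <- cells[cells$count_allele1 + cells$count_allele2 >= 1, ,
                   drop = FALSE]
    out <- lapply(split(cells, cells$group), function(g) {
        if (!nrow(g)) return(NULL)
        if (reference == "group") {
            refIdx <- if (sum(g$count_allele1) >= sum(g$count_allele2)) 1L
                      else 2L
            c1 <- if (refIdx == 1L) g$count_allele1 else g$count_allele2
            c2 <- if (refIdx == 1L) g$count_allele2 else g$count_allele1
            eff <- cellLogOdds(c1, c2, continuity, reference = "allele1")
            eff$reference_allele <- refIdx
        } else {
            eff <- cellLogOdds(g$count_allele1, g$count_allele2, continuity,
                               reference = "dominant")
            refIdx <- NA_integer_
        }
        pool <- poolRandomEffects(eff$log_odds, eff$variance)
        data.frame(group = g$group[1L],
                   summary_log_odds = pool$summary_log_odds,
                   standard_error = pool$standard_error,
                   tau2 = pool$tau2, n_cells = pool$n_cells,
                   reference_allele = if (reference == "group") refIdx
                                      else NA_integer_)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Correlation of genotyper-derived and truth-derived ASE summaries
#'
#' Squared Pearson correlation of paired summary log-odds, quantifying how
#' well ASE computed on a genotyper's (possibly wrong) reference alleles
#' tracks the ASE computed on the molecular genotype.
#'
#' @param summaryPred,summaryTruth numeric vectors of paired summary
#'   log-odds over the same samples x groups.
#' @return squared Pearson correlation.
#' @export
compareAseToTruth <- function(summaryPred, summaryTruth) {
    ok <- stats::complete.cases(summaryPred, summaryTruth)
    x <- summaryPred[ok]; y <- summaryTruth[ok]
    if (length(x) < 3L)
        stop("need at least 3 paired summaries for a correlation")
    stats::cor(x, y)^2
}
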