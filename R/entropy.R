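#' Positional diversity profile of an HLA alignment
#'
#' Per-column 2-bit Shannon entropy of a nucleotide multiple sequence
#' alignment together with a rolling (window) mean, used to show where in
#' a gene the allelic diversity concentrates (for HLA genes, towards the
#' 5' exons encoding the peptide-binding groove).
#'
#' @slot locus character label for the profiled locus.
#' @slot entropy numeric vector of per-column entropies in bits (`NA` for
#'   all-gap columns).
#' @slot rolling numeric vector of windowed mean entropies, same length.
#' @slot window integer window width in alignment positions.
#' @seealso [profileAlignment()]
#' @export
setClass("EntropyProfile",
    representation(locus = "character", entropy = "numeric",
                   rolling = "numeric", window = "integer"))

setValidity("EntropyProfile", function(object) {
    if (length(object@rolling) != length(object@entropy))
        return("rolling and per-position vectors must have equal length")
    e <- c(object@entropy, object@rolling)
    if (any(e < -1e-12 | e > 2 + 1e-12, na.rm = TRUE))
        return("entropy values must lie in [0, 2] bits")
    if (object@window < 1L) return("window must be >= 1")
    TRUE
})

#' @describeIn EntropyProfile per-position entropies (bits).
#' @param x an `EntropyProfile`.
#' @export
positionEntropy <- function(x) x@entropy

#' @describeIn EntropyProfile rolling-mean entropies (bits).
#' @export
rollingEntropy <- function(x) x@rolling

#' @describeIn EntropyProfile concise display.
#' @param object an `EntropyProfile`.
#' @export
setMethod("show", "EntropyProfile", function(object) {
    cat(sprintf(
        "EntropyProfile '%s': %d positions, window %d, mean %.3f bits\n",
        object@locus, length(object@entropy), object@window,
        mean(object@entropy, na.rm = TRUE)))
})

#' Shannon entropy of one alignment column
#'
#' Entropy is computed on the nucleotide frequencies among unambiguous
#' bases only: gaps (`-`), `N` and other ambiguity codes carry no identity
#' information (published HLA reference alleles often include only partial
#' exon sequence) and are excluded before frequencies are formed.  With the
#' four bases the maximum is 2 bits.
#'
#' @param column character vector of single characters (one per sequence).
#' @return entropy in bits; `NA` when the column holds no unambiguous base.
#' @examples
#' columnEntropy(c("A", "C", "G", "T"))   # 2 bits
#' columnEntropy(c("A", "A", "A", "C"))   # 0.811 bits
#' @export
columnEntropy <- function(column) {
    column <- toupper(as.character(column))
    base <- column[column %in% c("A", "C", "G", "T")]
    if (!length(base)) return(NA_real_)
    p <- table(base) / length(base)
    -sum(p * log2(p))
}

#' Entropy profile of a multiple sequence alignment
#'
#' Computes the per-column 2-bit Shannon entropy of an aligned set of
#' allele sequences and smooths it with a centered rolling mean (default
#' 100 bp).  Window edges use shrunken (partial) windows so the profile
#' keeps the alignment's length; all-gap columns are `NA` and are dropped
#' from any window mean covering them.
#'
#' @param msa a [Biostrings::DNAStringSet] of equal-width aligned sequences,
#'   or a character vector of aligned sequences, or a path to an aligned
#'   FASTA file.
#' @param window rolling window width in positions (default 100).
#' @param locus label stored in the profile.
#' @param align `"center"` (default) or `"trailing"` window placement.
#' @return an [EntropyProfile-class].
#' @export
profileAlignment <- function(msa, window = 100L, locus = "HLA",
                             align = c("center", "trailing")) {
    align <- match.arg(align)
    if (is.character(msa) && length(msa) == 1L && file.exists(msa))
        msa <- Biostrings::readDNAStringSet(msa)
    if (is.character(msa))
        msa <- Biostrings::DNAStringSet(msa)
    if (!is(msa, "XStringSet"))
        stop("msa must be a DNAStringSet, character vector or FASTA path")
    if (length(msa) < 2L)
        stop("an alignment needs at least 2 sequences")
    w <- unique(Biostrings::width(msa))
    if (length(w) != 1L)
        stop("ragged alignment: sequences have unequal aligned lengths")
    window <- as.integer(window)
    stopifnot(window >= 1L)

    cm <- Biostrings::consensusMatrix(msa)
    bases <- cm[intersect(rownames(cm), c("A", "C", "G", "T")), , drop = FALSE]
    tot <- colSums(bases)
    p <- sweep(bases, 2L, pmax(tot, 1L), "/")
    plogp <- ifelse(p > 0, p * log2(p), 0)
    ent <- -colSums(plogp)
    ent[tot == 0L] <- NA_real_

    new("EntropyProfile", locus = locus, entropy = as.numeric(ent),
        rolling = .rollMean(ent, window, align), window = window)
}

# partial-window rolling mean, NA-dropping; keeps input length
.rollMean <- function(x, window, align = "center") {
    n <- length(x)
    if (window == 1L) return(x)
    half <- (window - 1L) %/% 2L
    lo <- if (align == "center") pmax(1L, seq_len(n) - half)
          else pmax(1L, seq_len(n) - window + 1L)
    hi <- if (align == "center") pmin(n, seq_len(n) + (window - 1L - half))
          else seq_len(n)
    xs <- ifelse(is.na(x), 0, x)
    cs <- c(0, cumsum(xs))
    cn <- c(0L, cumsum(!is.na(x)))
    num <- cs[hi + 1L] - cs[lo]
    cnt <- cn[hi + 1L] - cn[lo]
    out <- ifelse(cnt > 0L, num / pmax(cnt, 1L), NA_real_)
    out
}

#' Write an entropy profile as a tidy table
#'
#' @param profile an [EntropyProfile-class].
#' @param path output TSV path.
#' @return the data.frame written, invisibly.
#' @export
writeEntropyProfile <- function(profile, path) {
    df <- data.frame(locus = profile@locus,
                     position = seq_along(profile@entropy),
                     entropy = profile@entropy,
                     rolling_entropy = profile@rolling)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
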