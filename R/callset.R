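#' Genotype callsets
#'
#' A `GenotypeCallset` holds the allele calls of one or more genotypers over
#' a cohort: one row per sample x genotyper x locus with up to two allele
#' columns (`allele1`, `allele2`; `NA` = no call for that slot).  When the
#' upstream tool emits a ranked allele list (abundance or score order),
#' `allele1` is the top-ranked call; set `ranked = TRUE` so that top-n
#' copy-number filtering is allowed to truncate the list.
#'
#' @slot calls data.frame with columns `sample_id`, `genotyper`, `locus`,
#'   `allele1`, `allele2` (character).
#' @slot ranked logical scalar; whether column order encodes the upstream
#'   genotyper's rank order.
#'
#' @seealso [readGenotypeTable()], [summarizeConcordance()]
#' @export
setClass("GenotypeCallset",
    representation(calls = "data.frame", ranked = "logical"))

.CALL_COLS <- c("sample_id", "genotyper", "locus", "allele1", "allele2")

setValidity("GenotypeCallset", function(object) {
    df <- object@calls
    if (!all(.CALL_COLS %in% names(df)))
        return(paste("calls must have columns",
                     paste(.CALL_COLS, collapse = ", ")))
    key <- paste(df$sample_id, df$genotyper, df$locus, sep = "\r")
    if (anyDuplicated(key))
        return("duplicated sample_id x genotyper x locus rows")
    if (length(object@ranked) != 1L || is.na(object@ranked))
        return("ranked must be TRUE or FALSE")
    for (col in c("allele1", "allele2")) {
        al <- df[[col]]
        ok <- is.na(al) | !nzchar(al)
        if (any(!ok)) {
            parsed <- parseAllele(al[!ok])   # errors on malformed names
            if (!all(alleleLocus(parsed) == df$locus[!ok]))
                return(sprintf("%s entries disagree with the locus column", col))
        }
    }
    TRUE
})

#' Construct a GenotypeCallset
#'
#' @param calls data.frame with columns `sample_id`, `genotyper`, `locus`,
#'   `allele1`, `allele2`; empty strings are treated as `NA` (no call).
#' @param ranked logical; does column order encode the genotyper's allele
#'   ranking?
#' @return a [GenotypeCallset-class] object.
#' @export
GenotypeCallset <- function(calls, ranked = FALSE) {
    calls <- as.data.frame(calls, stringsAsFactors = FALSE)
    for (col in c("sample_id", "genotyper", "locus", "allele1", "allele2")) {
        if (!col %in% names(calls))
            stop(sprintf("missing column '%s'", col))
        calls[[col]] <- as.character(calls[[col]])
    }
    for (col in c("allele1", "allele2"))
        calls[[col]][!is.na(calls[[col]]) & !nzchar(calls[[col]])] <- NA_character_
    # slot-2-only calls are promoted so that allele1 is always filled first
    swap <- is.na(calls$allele1) & !is.na(calls$allele2)
    if (any(swap)) {
        calls$allele1[swap] <- calls$allele2[swap]
        calls$allele2[swap] <- NA_character_
    }
    rownames(calls) <- NULL
    new("GenotypeCallset", calls = calls[, .CALL_COLS], ranked = ranked)
}

#' @describeIn GenotypeCallset the underlying calls data.frame.
#' @param x a `GenotypeCallset`.
#' @export
callTable <- function(x) x@calls

#' @describeIn GenotypeCallset sample identifiers present.
#' @export
callsetSamples <- function(x) unique(x@calls$sample_id)

#' @describeIn GenotypeCallset genotyper names present.
#' @export
callsetGenotypers <- function(x) unique(x@calls$genotyper)

#' @describeIn GenotypeCallset loci present.
#' @export
callsetLoci <- function(x) unique(x@calls$locus)

#' @describeIn GenotypeCallset whether allele columns are rank-ordered.
#' @export
isRanked <- function(x) x@ranked

#' @describeIn GenotypeCallset concise display.
#' @param object a `GenotypeCallset`.
#' @export
setMethod("show", "GenotypeCallset", function(object) {
    df <- object@calls
    cat(sprintf(
        "GenotypeCallset: %d calls | %d samples | %d genotypers | %d loci%s\n",
        nrow(df), length(unique(df$sample_id)),
        length(unique(df$genotyper)), length(unique(df$locus)),
        if (object@ranked) " | ranked" else ""))
    if (nrow(df)) print(utils::head(df, 4L))
})

# alleles called at one sample/genotyper/locus, as character (may be length 0)
.callAlleles <- function(x, sample, genotyper, locus) {
    df <- x@calls
    row <- df[df$sample_id == sample & df$genotyper == genotyper &
              df$locus == locus, , drop = FALSE]
    if (!nrow(row)) return(character(0L))
    al <- c(row$allele1[1L], row$allele2[1L])
    al[!is.na(al)]
}

#' Keep a subset of genotypers
#' @param x a [GenotypeCallset-class].
#' @param genotypers character vector of genotyper names to keep.
#' @export
subsetGenotypers <- function(x, genotypers) {
    GenotypeCallset(x@calls[x@calls$genotyper %in% genotypers, , drop = FALSE],
                    ranked = x@ranked)
}
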