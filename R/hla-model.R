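#' @import methods
NULL

#' Parsed HLA allele names
#'
#' `HlaAllele` is a vectorized S4 container for HLA allele names in
#' colon-delimited nomenclature (`locus*F1:F2:F3:F4` with an optional
#' one-letter expression suffix such as `N` for null alleles).  Field digits
#' are kept verbatim, so `A*02:01` and `A*2:1` are distinct objects.
#'
#' @slot locus character vector of locus symbols (e.g. `"A"`, `"DRB1"`).
#' @slot fields list of character vectors, one per allele, each holding 1-4
#'   digit-only fields in order.
#' @slot suffix character vector of expression suffixes (`NA` when absent);
#'   one of `N`, `L`, `S`, `C`, `A`, `Q`.
#'
#' @seealso [parseAllele()], [truncateAllele()], [allelesMatch()]
#' @export
setClass("HlaAllele",
    representation(locus = "character", fields = "list", suffix = "character"))

.VALID_SUFFIX <- c("N", "L", "S", "C", "A", "Q")

setValidity("HlaAllele", function(object) {
    n <- length(object@locus)
    if (length(object@fields) != n || length(object@suffix) != n)
        return("locus, fields and suffix must have equal length")
    for (f in object@fields) {
        if (length(f) < 1L || length(f) > 4L)
            return("each allele must carry 1-4 fields")
        if (!all(grepl("^[0-9]+$", f)))
            return("allele fields must contain only digits")
    }
    bad <- !is.na(object@suffix) & !object@suffix %in% .VALID_SUFFIX
    if (any(bad))
        return(sprintf("invalid expression suffix '%s'",
                       object@suffix[bad][1L]))
    TRUE
})

#' @describeIn HlaAllele number of alleles in the vector.
#' @param x an `HlaAllele` object.
#' @export
setMethod("length", "HlaAllele", function(x) length(x@locus))

#' @describeIn HlaAllele subset alleles.
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "HlaAllele", function(x, i, j, ..., drop = TRUE) {
    new("HlaAllele", locus = x@locus[i], fields = x@fields[i],
        suffix = x@suffix[i])
})

#' @describeIn HlaAllele display canonical allele names.
#' @param object an `HlaAllele` object.
#' @export
setMethod("show", "HlaAllele", function(object) {
    cat("HlaAllele of length", length(object), "\n")
    if (length(object))
        print(formatAllele(object))
})

#' @describeIn HlaAllele locus symbol accessor.
#' @export
alleleLocus <- function(x) x@locus

#' @describeIn HlaAllele list of per-allele field vectors.
#' @export
alleleFields <- function(x) x@fields

#' @describeIn HlaAllele expression suffix accessor (`NA` when absent).
#' @export
alleleSuffix <- function(x) x@suffix

#' Parse HLA allele names
#'
#' Parses colon-delimited HLA nomenclature into an [HlaAllele] object.  A
#' leading `HLA-` prefix and lower-case input are normalized away; G/P group
#' names (e.g. `A*01:01:01G`) are rejected because they denote allele groups,
#' not single alleles.
#'
#' @param name character vector of allele names, e.g. `"HLA-A*02:01"`,
#'   `"DRB1*15:01:01"`, `"A*24:09N"`.
#' @return an [HlaAllele] of the same length.
#' @examples
#' a <- parseAllele(c("HLA-A*02:01", "DRB1*15:01:01", "A*24:09N"))
#' formatAllele(a)
#' @export
parseAllele <- function(name) {
    name <- as.character(name)
    n <- length(name)
    locus <- character(n); suffix <- rep(NA_character_, n)
    fields <- vector("list", n)
    for (i in seq_len(n)) {
        s <- name[i]
        if (is.na(s) || !nzchar(s))
            stop("cannot parse empty allele name")
        s0 <- toupper(trimws(s))
        s0 <- sub("^HLA-", "", s0)
        if (!grepl("*", s0, fixed = TRUE))
            stop(sprintf("malformed allele name '%s': missing '*' separator", s))
        parts <- strsplit(s0, "*", fixed = TRUE)[[1L]]
        if (length(parts) != 2L || !nzchar(parts[1L]))
            stop(sprintf("malformed allele name '%s': bad locus token", s))
        loc <- parts[1L]
        if (!grepl("^[A-Z][A-Z0-9]*$", loc))
            stop(sprintf("malformed allele name '%s': invalid locus '%s'",
                         s, loc))
        rest <- parts[2L]
        suf <- NA_character_
        last <- substr(rest, nchar(rest), nchar(rest))
        if (grepl("[A-Z]", last)) {
            if (last %in% c("G", "P"))
                stop(sprintf(
                    "allele '%s' is a %s-group name; supply a plain allele",
                    s, last))
            if (!last %in% .VALID_SUFFIX)
                stop(sprintf(
                    "malformed allele name '%s': unknown suffix '%s'", s, last))
            suf <- last
            rest <- substr(rest, 1L, nchar(rest) - 1L)
        }
        fld <- strsplit(rest, ":", fixed = TRUE)[[1L]]
        if (length(fld) < 1L || length(fld) > 4L ||
            !all(nzchar(fld)) || !all(grepl("^[0-9]+$", fld)))
            stop(sprintf(
                "malformed allele name '%s': non-digit or empty field in '%s'",
                s, rest))
        locus[i] <- loc; fields[[i]] <- fld; suffix[i] <- suf
    }
    new("HlaAllele", locus = locus, fields = fields, suffix = suffix)
}

#' Canonical string form of HLA alleles
#'
#' @param a an [HlaAllele] object.
#' @return character vector, e.g. `"A*02:01"` or `"A*24:09N"`.
#' @export
formatAllele <- function(a) {
    stopifnot(is(a, "HlaAllele"))
    out <- vapply(seq_along(a@locus), function(i) {
        s <- paste0(a@locus[i], "*", paste(a@fields[[i]], collapse = ":"))
        if (!is.na(a@suffix[i])) s <- paste0(s, a@suffix[i])
        s
    }, character(1L))
    out
}

#' Truncate HLA alleles to a field resolution
#'
#' Keeps the first `min(fieldLevel, available)` fields; no padding is
#' invented when the allele carries fewer fields than requested.  The
#' expression suffix is dropped whenever fields are removed (it qualifies
#' the full-resolution name only).
#'
#' @param a an [HlaAllele] or character vector of allele names.
#' @param fieldLevel integer in 1..4.
#' @return object of the same type as `a`.
#' @examples
#' truncateAllele("A*02:01:01", 2)   # "A*02:01"
#' @export
truncateAllele <- function(a, fieldLevel) {
    stopifnot(length(fieldLevel) == 1L, fieldLevel >= 1L)
    chr <- is.character(a)
    if (chr) a <- parseAllele(a)
    stopifnot(is(a, "HlaAllele"))
    fieldLevel <- as.integer(fieldLevel)
    fields <- lapply(a@fields, function(f) f[seq_len(min(fieldLevel, length(f)))])
    suffix <- ifelse(lengths(a@fields) > fieldLevel, NA_character_, a@suffix)
    out <- new("HlaAllele", locus = a@locus, fields = fields, suffix = suffix)
    if (chr) formatAllele(out) else out
}

#' Compare two alleles at a field resolution
#'
#' Two alleles match at level `f` when their loci are equal and their first
#' `f` fields agree exactly.  The comparison is on the full prefix: `A*02:01`
#' vs `A*01:01` do not match at field 2 even though the second field agrees.
#' The strict depth rule is used: alleles match at level `f` iff their
#' truncations to `f` fields are identical, so a 2-field call can never
#' match a 3-field truth allele at field 3 (it makes no claim there, and
#' counting it would inflate deep-field accuracy), while two identical
#' 2-field names still match at every level.
#'
#' @param a,b [HlaAllele] objects or character allele names; recycled to a
#'   common length.
#' @param fieldLevel integer field resolution (1..4).
#' @return logical vector.
#' @examples
#' allelesMatch("A*02:01", "A*02:05", 1)  # TRUE
#' allelesMatch("A*02:01", "A*02:05", 2)  # FALSE
#' @export
allelesMatch <- function(a, b, fieldLevel) {
    stopifnot(length(fieldLevel) == 1L, fieldLevel >= 1L)
    if (is.character(a)) a <- parseAllele(a)
    if (is.character(b)) b <- parseAllele(b)
    ca <- formatAllele(truncateAllele(a, fieldLevel))
    cb <- formatAllele(truncateAllele(b, fieldLevel))
    n <- max(length(ca), length(cb))
    rep_len(ca, n) == rep_len(cb, n)
}
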