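#' Supported classical HLA loci
#'
#' Loci handled by the cohort data model, in canonical order: the class I
#' loci A, B, C and the class II loci DQA1, DQB1, DRB1.
#'
#' @export
HLA_LOCI <- c("A", "B", "C", "DQA1", "DQB1", "DRB1")

.allele_regex <- "^(A|B|C|DQA1|DQB1|DRB1)\\*([0-9]{2,3})(:([0-9]{2,3}))?$"

#' Parse classical HLA allele names
#'
#' Parses WHO-nomenclature allele strings such as `"B*57:01"` (four-digit,
#' i.e. two-field) or `"C*06"` (two-digit). `NA`, the empty string and
#' `"NA"` are treated as missing calls and preserved as such.
#'
#' @param x Character vector of allele names.
#' @param locus Optional locus each allele must belong to; a mismatch
#'   between the locus encoded in the name and this argument is an error.
#' @return A data.frame with one row per input: `name` (normalised string),
#'   `locus`, `resolution` (`"two_digit"` or `"four_digit"`), `missing`.
#' @examples
#' parse_allele(c("B*57:01", "C*06", NA))
#' @export
parse_allele <- function(x, locus = NULL) {
  x <- as.character(x)
  missing <- is.na(x) | x == "" | x == "NA"
  m <- regmatches(x, regexec(.allele_regex, x))
  bad <- !missing & lengths(m) == 0
  if (any(bad)) {
    stop_fm(
      "unparseable allele string(s): ",
      paste(sprintf("'%s'", utils::head(x[bad], 5L)), collapse = ", ")
    )
  }
  loc <- ifelse(missing, NA_character_, vapply(m, function(g) {
    if (length(g)) g[2L] else NA_character_
  }, character(1)))
  field2 <- ifelse(missing, NA_character_, vapply(m, function(g) {
    if (length(g)) g[5L] else NA_character_
  }, character(1)))
  if (!is.null(locus)) {
    mism <- !missing & loc != locus
    if (any(mism)) {
      stop_fm(
        "allele '", x[which(mism)[1L]], "' does not belong to locus ", locus
      )
    }
  }
  data.frame(
    name = ifelse(missing, NA_character_, x),
    locus = loc,
    resolution = ifelse(missing, NA_character_,
                        ifelse(is.na(field2) | field2 == "", "two_digit", "four_digit")),
    missing = missing,
    stringsAsFactors = FALSE
  )
}

#' Truncate allele names to two-digit resolution
#'
#' Collapses a four-digit (two-field) allele to its first field, e.g.
#' `"B*57:01"` to `"B*57"`. Two-digit names and missing calls pass through.
#'
#' @param x Character vector of allele names.
#' @return Character vector of two-digit names.
#' @export
allele_two_digit <- function(x) {
  sub(":.*$", "", x)
}

# Locus encoded in an allele name ("B*57:01" -> "B"); NA passes through.
allele_locus <- function(x) {
  sub("\\*.*$", "", x)
}
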