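# ATC code grammar and prefix matching.
#
# WHO ATC codes are hierarchical: one letter (anatomical group), two digits
# (therapeutic subgroup), one letter (pharmacological subgroup), one letter
# (chemical subgroup), two digits (substance). A valid term is a full code or
# any truncation at a level boundary, giving string lengths 1, 3, 4, 5, 7.

.atc_patterns <- c(
  "1" = "^[A-Z]$",
  "3" = "^[A-Z][0-9]{2}$",
  "4" = "^[A-Z][0-9]{2}[A-Z]$",
  "5" = "^[A-Z][0-9]{2}[A-Z]{2}$",
  "7" = "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
)

# Logical vector: which already upper-cased/stripped strings are valid terms.
atc_ok <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(FALSE)
    }
    pat <- .atc_patterns[as.character(nchar(s))]
    !is.na(pat) && grepl(pat, s)
  }, logical(1), USE.NAMES = FALSE)
}

#' Validate and normalise ATC codes
#'
#' Upper-cases and strips whitespace, then checks each code against the ATC
#' grammar: a letter, two digits, two letters, two digits, truncated only at
#' a classification-level boundary (lengths 1, 3, 4, 5, or 7 characters).
#' Terms at any level are accepted, so `"L01"` (antineoplastic agents) is as
#' valid as `"L01XX05"`.
#'
#' @param code Character vector of ATC codes or prefixes.
#'
#' @return The normalised codes, same length as `code`. The function is
#'   idempotent: validating an already-normalised code returns it unchanged.
#'
#' @examples
#' validate_atc(c(" l01xx05", "N02BE01", "A02"))
#' @export
validate_atc <- function(code) {
  if (length(code) == 0) {
    stop("no ATC code supplied", call. = FALSE)
  }
  x <- toupper(gsub("[[:space:]]+", "", as.character(code)))
  bad <- !atc_ok(x)
  if (any(bad)) {
    offenders <- unique(as.character(code)[bad])
    stop(
      "invalid ATC code(s): ",
      paste(sprintf("'%s'", offenders), collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Test whether ATC codes fall under a term
#'
#' Prefix semantics: a term at any ATC level matches itself and all of its
#' descendants, so `"L01"` matches every antineoplastic substance code.
#'
#' @param code Character vector of validated ATC codes.
#' @param term A single validated ATC term (any level).
#'
#' @return Logical vector, one element per code.
#' @examples
#' atc_matches(c("L01XX05", "L02AE02"), "L01")
#' @export
atc_matches <- function(code, term) {
  stopifnot(length(term) == 1)
  startsWith(code, term)
}

# Truncate codes to a coarser ATC level (1..5). Codes already coarser than
# the requested level are left as given.
atc_truncate <- function(code, level) {
  stopifnot(level %in% 1:5)
  width <- c(1L, 3L, 4L, 5L, 7L)[level]
  substr(code, 1L, pmin(nchar(code), width))
}
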