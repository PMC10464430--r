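#' Normalize ICD-10 codes
#'
#' Brings raw ICD-10 strings into the canonical form used throughout the
#' package: uppercase, dot removed, truncated to at most four characters
#' (the letter, two digits, and an optional fourth alphanumeric character).
#' Normalization is idempotent.
#'
#' @param raw Character vector of raw ICD-10 codes (e.g. `"I50.9"`, `"r99"`).
#' @param strict If `TRUE` (default), malformed codes raise an error naming
#'   the offending strings; if `FALSE`, malformed codes become `NA`.
#'
#' @return Character vector of normalized codes, e.g. `"I509"`, `"R99"`.
#' @examples
#' normalize_icd(c("I50.9", "r99", "C55"))
#' @export
normalize_icd <- function(raw, strict = TRUE) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(gsub("[.[:space:]]", "", as.character(raw)))
  x <- substr(x, 1L, 4L)
  ok <- grepl("^[A-Z][0-9]{2}[A-Z0-9]?$", x)
  ok[is.na(x)] <- FALSE
  if (any(!ok)) {
    if (strict) {
      bad <- unique(raw[!ok])
      stop("Malformed ICD-10 code(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "",
           call. = FALSE)
    }
    x[!ok] <- NA_character_
  }
  x
}

#' @keywords internal
is_icd_prefix <- function(x) grepl("^[A-Z][0-9]{2}[A-Z0-9]?$", x)

# Longest-prefix lookup of normalized codes against a table of 3/4-char
# prefixes: a 4-char entry shadows its 3-char parent. Returns integer row
# indices into `prefixes` (NA where nothing matches).
match_icd_prefix <- function(codes, prefixes) {
  idx4 <- match(codes, prefixes)                 # exact (incl. 4-char entries)
  idx3 <- match(substr(codes, 1L, 3L), prefixes) # fall back to 3-char parent
  ifelse(is.na(idx4), idx3, idx4)
}

# TRUE where `codes` matches any prefix in `set` (either the code starts with
# a set member, or -- for 3-char codes -- a set member starts with the code).
icd_in_set <- function(codes, set) {
  if (length(set) == 0L) return(rep(FALSE, length(codes)))
  hit <- codes %in% set | substr(codes, 1L, 3L) %in% set
  # a 3-char code also matches 4-char set members that extend it
  set3 <- substr(set, 1L, 3L)
  hit | (nchar(codes) == 3L & codes %in% set3)
}
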