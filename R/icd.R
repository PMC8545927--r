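# ICD-9-CM code handling: validation, canonical (dot-free) storage,
# truncation to the node granularity used when building disease networks.

icd_regex <- "^(\\d{3}(\\.\\d{1,2})?|[EeVv]\\d{2,3}(\\.\\d{1,2})?)$"
icd_canonical_regex <- "^(\\d{3,5}|[EV]\\d{2,5})$"

#' Canonicalize ICD-9-CM codes
#'
#' Accepts codes with or without the decimal point (`"250.01"` or `"25001"`)
#' and returns the canonical dot-free upper-case form. Malformed codes raise
#' an error naming the offending value.
#'
#' @param codes Character vector of ICD-9-CM codes (3-5 digits, optionally
#'   E/V prefixed).
#' @return Character vector of canonical codes.
#' @examples
#' icd_canonicalize(c("250.01", "4019", "V27"))
#' @export
icd_canonicalize <- function(codes) {
  codes <- toupper(trimws(as.character(codes)))
  out <- gsub(".", "", codes, fixed = TRUE)
  bad <- !is.na(codes) & !(grepl(icd_regex, codes) | grepl(icd_canonical_regex, codes))
  if (any(bad)) {
    abort(sprintf(
      "Malformed ICD-9-CM code(s): %s",
      paste(unique(codes[bad]), collapse = ", ")
    ), class = "comorbnet_parse_error")
  }
  out[is.na(codes)] <- NA_character_
  out
}

#' Truncate ICD-9-CM codes to a node granularity
#'
#' @param codes Canonical or dotted ICD-9-CM codes.
#' @param level Integer, 3 (disease family), 4 or 5 digits. E/V codes keep
#'   their prefix letter plus `level` digits at most.
#' @return Character vector of truncated canonical codes.
#' @export
icd_truncate <- function(codes, level = 3) {
  stopifnot(level %in% c(3, 4, 5))
  codes <- icd_canonicalize(codes)
  ev <- grepl("^[EV]", codes)
  out <- substr(codes, 1, level)
  out[which(ev)] <- substr(codes[which(ev)], 1, level + 1L)
  out
}

icd_root_number <- function(codes) {
  codes <- icd_canonicalize(codes)
  num <- suppressWarnings(as.integer(substr(codes, 1, 3)))
  num[grepl("^[EV]", codes)] <- NA_integer_
  num
}
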