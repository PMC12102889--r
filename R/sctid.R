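# SNOMED CT identifier (SCTID) syntax checks. SCTIDs are 6-18 digit strings
# whose final digit is a Verhoeff check digit; they are always handled as
# text, never parsed as numbers (leading characters must survive round-trips
# and 18 digits overflow doubles).

# Verhoeff dihedral-group tables.
.verhoeff_d <- matrix(c(
  0, 1, 2, 3, 4, 5, 6, 7, 8, 9,
  1, 2, 3, 4, 0, 6, 7, 8, 9, 5,
  2, 3, 4, 0, 1, 7, 8, 9, 5, 6,
  3, 4, 0, 1, 2, 8, 9, 5, 6, 7,
  4, 0, 1, 2, 3, 9, 5, 6, 7, 8,
  5, 9, 8, 7, 6, 0, 4, 3, 2, 1,
  6, 5, 9, 8, 7, 1, 0, 4, 3, 2,
  7, 6, 5, 9, 8, 2, 1, 0, 4, 3,
  8, 7, 6, 5, 9, 3, 2, 1, 0, 4,
  9, 8, 7, 6, 5, 4, 3, 2, 1, 0
), nrow = 10, byrow = TRUE)

.verhoeff_p <- matrix(c(
  0, 1, 2, 3, 4, 5, 6, 7, 8, 9,
  1, 5, 7, 6, 2, 8, 3, 0, 9, 4,
  5, 8, 0, 3, 7, 9, 6, 1, 4, 2,
  8, 9, 1, 6, 0, 4, 3, 5, 2, 7,
  9, 4, 5, 3, 1, 2, 6, 8, 7, 0,
  4, 2, 8, 6, 5, 7, 3, 9, 0, 1,
  2, 7, 9, 3, 8, 0, 6, 4, 1, 5,
  7, 0, 4, 6, 9, 1, 3, 2, 5, 8
), nrow = 8, byrow = TRUE)

.verhoeff_inv <- c(0, 4, 3, 2, 1, 5, 6, 7, 8, 9)

verhoeff_checksum <- function(digits_reversed) {
  c <- 0L
  for (i in seq_along(digits_reversed)) {
    c <- .verhoeff_d[c + 1L, .verhoeff_p[((i - 1L) %% 8L) + 1L, digits_reversed[i] + 1L] + 1L]
  }
  c
}

verhoeff_valid <- function(id) {
  digits <- rev(as.integer(strsplit(id, "", fixed = TRUE)[[1]]))
  verhoeff_checksum(digits) == 0L
}

#' Append a Verhoeff check digit to a digit string
#'
#' Used by the synthetic vocabulary generator so generated identifiers also
#' pass strict validation.
#'
#' @param body Character vector of digit strings (identifier without the check
#'   digit).
#' @return `body` with one check digit appended to each element.
#' @export
verhoeff_complete <- function(body) {
  vapply(body, function(b) {
    digits <- rev(as.integer(strsplit(b, "", fixed = TRUE)[[1]]))
    # position 1 is reserved for the (unknown) check digit
    c <- 0L
    for (i in seq_along(digits)) {
      c <- .verhoeff_d[c + 1L, .verhoeff_p[(i %% 8L) + 1L, digits[i] + 1L] + 1L]
    }
    paste0(b, .verhoeff_inv[c + 1L])
  }, character(1), USE.NAMES = FALSE)
}

#' Validate SNOMED CT identifier syntax
#'
#' An SCTID is syntactically valid when it is digits-only with length 6-18.
#' With `strict = TRUE` the trailing Verhoeff check digit is verified as well
#' (all released SNOMED CT identifiers carry one).
#'
#' @param code_id Character vector of candidate identifiers.
#' @param strict Also verify the Verhoeff check digit?
#' @return Logical vector; `FALSE` for malformed input (never an error).
#' @examples
#' validate_sctid(c("195967001", "281239006", "12a45", ""))
#' @export
validate_sctid <- function(code_id, strict = FALSE) {
  if (length(code_id) == 0L) return(logical(0))
  code_id <- as.character(code_id)
  ok <- !is.na(code_id) & grepl("^[0-9]{6,18}$", code_id)
  if (strict && any(ok)) {
    ok[ok] <- vapply(code_id[ok], verhoeff_valid, logical(1), USE.NAMES = FALSE)
  }
  ok
}
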