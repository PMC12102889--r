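# Condition-name normalisation.
#
# Baseline codelists name the same clinical concept inconsistently: spaces vs
# underscores, capitalisation, trailing plurals, and parenthesised
# abbreviations ("Chronic Obstructive Pulmonary Disease (COPD)"). All matching
# in the package happens on a canonical key derived here; the raw display name
# is preserved on the codelist itself.

#' Default plural-stripping exception terms
#'
#' Tokens that end in "s" but are not plurals and must never be stripped when
#' deriving canonical condition keys. Tokens ending in "ss", "is" or "us"
#' (sepsis, arthritis, tinnitus, mellitus, ...) are already protected by the
#' suffix rule; this list covers the remainder (Latin/Greek singulars and
#' uncountables common in condition names).
#'
#' @return A character vector of lower-case tokens.
#' @export
plural_exception_terms <- function() {
  c(
    "varices", "diabetes", "measles", "herpes", "rabies", "scabies",
    "caries", "species", "series", "ascites", "pubis", "forceps"
  )
}

strip_plural_token <- function(token, exceptions) {
  keep <- nchar(token) <= 3L |
    grepl("(ss|is|us)$", token) |
    !grepl("s$", token) |
    token %in% exceptions
  ifelse(keep, token, sub("s$", "", token))
}

normalize_one <- function(name, plural_exceptions) {
  trimmed <- trimws(name)
  if (!nzchar(trimmed)) {
    stop_invalid("Condition name is empty or whitespace-only.")
  }
  # Parenthesised content (usually an abbreviation) is not part of the key;
  # extract_aliases() surfaces it separately.
  base <- gsub("\\([^)]*\\)", " ", trimmed)
  if (!nzchar(trimws(gsub("[^[:alnum:]]", "", base)))) {
    # Name was entirely parenthetical, e.g. "(COPD)": fall back to the content.
    base <- gsub("[()]", " ", trimmed)
  }
  x <- tolower(base)
  x <- gsub("[_-]", " ", x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tokens <- strsplit(x, " ", fixed = TRUE)[[1]]
  paste(strip_plural_token(tokens, plural_exceptions), collapse = " ")
}

#' Normalise a condition name to its canonical key
#'
#' Produces the deterministic, idempotent key under which all condition-name
#' matching happens: case-folded, underscores/hyphens treated as spaces,
#' punctuation removed, whitespace collapsed, parenthesised content dropped
#' (it becomes an alias, see [extract_aliases()]), and per-token plural "s"
#' stripped for tokens longer than three characters that do not end in "ss",
#' "is" or "us" and are not in the exception list.
#'
#' @param name Character vector of condition names.
#' @param plural_exceptions Lower-case tokens exempt from plural stripping.
#' @return Character vector of canonical keys, same length as `name`.
#' @examples
#' normalize_condition_name(c("Pulmonary hypertension", "pulmonary_hypertension"))
#' normalize_condition_name("alcohol problems")
#' @export
normalize_condition_name <- function(name,
                                     plural_exceptions = plural_exception_terms()) {
  if (!is.character(name) || length(name) == 0L) {
    stop_invalid("`name` must be a non-empty character vector.")
  }
  vapply(name, normalize_one, character(1),
    plural_exceptions = plural_exceptions, USE.NAMES = FALSE
  )
}

#' Extract the alias set of a condition name
#'
#' Returns the canonical key plus any parenthesised abbreviation as separate
#' normalised aliases, so "Chronic Obstructive Pulmonary Disease (COPD)" and a
#' bare "COPD" entry in another baseline can be recognised as the same
#' concept. Degenerate parentheses (empty content) contribute nothing.
#'
#' @param name A single condition name.
#' @inheritParams normalize_condition_name
#' @return Sorted character vector of aliases; always contains the canonical
#'   key.
#' @examples
#' extract_aliases("Chronic Obstructive Pulmonary Disease (COPD)")
#' @export
extract_aliases <- function(name, plural_exceptions = plural_exception_terms()) {
  if (!is.character(name) || length(name) != 1L) {
    stop_invalid("`name` must be a single character string.")
  }
  key <- normalize_condition_name(name, plural_exceptions)
  inner <- regmatches(name, gregexpr("\\(([^)]*)\\)", name))[[1]]
  inner <- gsub("[()]", "", inner)
  inner <- inner[nzchar(trimws(inner))]
  extra <- if (length(inner)) {
    normalize_condition_name(inner, plural_exceptions)
  } else {
    character(0)
  }
  sort(unique(c(key, extra)))
}

# Matching key for free-text terms/keywords: case-folded, punctuation as
# spaces, whitespace collapsed. No plural stripping — code terms are matched
# as written.
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}
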