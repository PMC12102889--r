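# Draft codelist generation: keyword search across preprocessed (SNOMED)
# collections, and directive-driven grouping/splitting. Keyword matching is
# case-insensitive, whitespace-normalised substring matching by default
# (so "alcohol" captures "Alcoholic liver disease"); a whole-word mode is
# available when that over-captures.

term_matches <- function(terms, keywords, whole_word = FALSE) {
  terms_n <- normalize_text(terms)
  kw_n <- normalize_text(keywords)
  hit <- rep(FALSE, length(terms_n))
  for (kw in kw_n) {
    if (whole_word) {
      pattern <- paste0("\\b", gsub("([\\W])", "\\\\\\1", kw, perl = TRUE), "\\b")
      hit <- hit | grepl(pattern, terms_n, perl = TRUE)
    } else {
      hit <- hit | grepl(kw, terms_n, fixed = TRUE)
    }
  }
  hit
}

#' Keyword search for candidate codes
#'
#' Fetches every code in the given collections whose term contains any
#' keyword; provenance gains a `<source>:<condition>` label recording the
#' originating list. Duplicates are merged; results are sorted by code id.
#'
#' @param keywords Non-empty character vector of search keywords.
#' @param collections One or more preprocessed (SNOMED-mapped)
#'   `codelist_collection`s, or a single list of them.
#' @param condition_name Name given to the resulting draft codelist.
#' @param whole_word Match keywords as whole words instead of substrings?
#' @return A draft `codelist` (status of harvested entries reset to `draft`).
#' @export
keyword_search_codes <- function(keywords, collections,
                                 condition_name = "draft",
                                 whole_word = FALSE) {
  if (length(keywords) == 0L || any(!nzchar(trimws(keywords)))) {
    stop_invalid("`keywords` must be non-empty strings.")
  }
  if (inherits(collections, "codelist_collection")) {
    collections <- list(collections)
  }
  rows <- list()
  for (coll in collections) {
    for (cl in coll$lists) {
      e <- entries(cl)
      hit <- term_matches(e$term, keywords, whole_word)
      if (!any(hit)) next
      sub <- e[hit, , drop = FALSE]
      sub$provenance <- prov_union(
        sub$provenance,
        paste0(coll$source_label, ":", canonical_key(cl))
      )
      sub$status <- "draft"
      rows[[length(rows) + 1L]] <- sub
    }
  }
  ent <- if (length(rows)) dplyr::bind_rows(rows) else code_entries(character(0), character(0))
  codelist(condition_name, ent)
}

collection_conditions <- function(collection) {
  derive_definitive_conditions(list(collection))
}

#' Apply a group directive to a collection
#'
#' Finds the related codelists (via [find_related_conditions()] over the
#' collection's own condition names), merges them with [merge_codelists()]
#' under the directive's merged name, and removes the source lists. With no
#' related list this is a no-op with a warning.
#'
#' @param directive A one-row `condition_directives` tibble with
#'   `action = "group"`.
#' @param collection A `codelist_collection`.
#' @return The restructured collection.
#' @export
apply_group <- function(directive, collection) {
  stopifnot(nrow(directive) == 1L)
  if (directive$action != "group") {
    stop_config("apply_group() requires a 'group' directive.")
  }
  related <- find_related_conditions(directive, collection_conditions(collection))
  related <- intersect(related, names(collection))
  if (length(related) == 0L) {
    rlang::warn(paste0(
      "Group directive for '", directive$condition,
      "' matched no codelists; collection unchanged."
    ))
    return(collection)
  }
  merged <- merge_codelists(collection$lists[related],
    merged_name = directive$targets[[1]][1]
  )
  collection_add(collection_drop(collection, related), merged)
}

#' Apply a split directive to a collection
#'
#' Every code of the source list is assigned to exactly one target: the
#' highest-priority rule (rank 1 first) whose keyword matches its term.
#' Unmatched codes go to an implicit lowest-priority fallback list
#' `"<Condition> Other"`, which is always materialised even when empty. The
#' union of the targets equals the source entry set (a true partition).
#'
#' @param directive A one-row `condition_directives` tibble with
#'   `action = "split"`.
#' @param rules Split-rule tibble (`condition`, `target`, `keywords`
#'   list-column, `priority`); rules for other conditions are ignored.
#' @param collection A `codelist_collection` containing the source list.
#' @param whole_word Passed to the keyword matcher.
#' @return The restructured collection (source removed, targets added).
#' @export
apply_split <- function(directive, rules, collection, whole_word = FALSE) {
  stopifnot(nrow(directive) == 1L)
  if (directive$action != "split") {
    stop_config("apply_split() requires a 'split' directive.")
  }
  key <- directive$canonical_key
  source_cl <- collection$lists[[key]]
  if (is.null(source_cl)) {
    stop_dependency(paste0("No codelist '", key, "' in the collection to split."))
  }
  rules <- rules[normalize_condition_name(rules$condition) == key, , drop = FALSE]
  if (nrow(rules) == 0L) {
    stop_config(paste0("No split rules supplied for '", directive$condition, "'."))
  }
  if (anyDuplicated(rules$priority)) {
    stop_config(paste0(
      "Duplicate split-rule priorities for '", directive$condition, "': ",
      toString(rules$priority[duplicated(rules$priority)])
    ))
  }
  uncovered <- setdiff(
    normalize_condition_name(directive$targets[[1]]),
    normalize_condition_name(rules$target)
  )
  if (length(uncovered)) {
    stop_config(paste0(
      "Split rules do not cover directive target(s): ", toString(uncovered)
    ))
  }
  rules <- rules[order(rules$priority), , drop = FALSE]

  e <- entries(source_cl)
  assigned <- rep(NA_integer_, nrow(e))
  for (r in seq_len(nrow(rules))) {
    hit <- term_matches(e$term, rules$keywords[[r]], whole_word)
    assigned[is.na(assigned) & hit] <- r
  }
  fallback_name <- paste(condition_name(source_cl), "Other")
  target_names <- c(rules$target, fallback_name)
  assigned[is.na(assigned)] <- length(target_names)

  out <- collection_drop(collection, key)
  for (t in seq_along(target_names)) {
    out <- collection_add(out, codelist(
      target_names[t], e[assigned == t, , drop = FALSE]
    ))
  }
  out
}
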