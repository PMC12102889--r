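# Core domain objects.
#
# A codelist is a named clinical concept plus a set of code entries; a
# collection is a keyed set of codelists from one source (a baseline release,
# a trusted phenotype library, or a pipeline stage output). Entries are held
# in a tibble with a fixed column set so every stage round-trips through the
# same CSV contract.

ONTOLOGIES <- c("SNOMED", "READ_V2", "CTV3", "MEDCODE", "DMD")
LEGACY_ONTOLOGIES <- setdiff(ONTOLOGIES, "SNOMED")
STATUSES <- c("draft", "needs_review", "auto_validated", "approved", "excluded")
# Validation lattice used when merging entries: a more validated status wins;
# "excluded" is sticky and beats everything.
.status_rank <- c(draft = 0L, needs_review = 1L, auto_validated = 2L, approved = 3L)

ENTRY_COLS <- c("ontology", "code_id", "term", "provenance", "status", "boundary_case")

#' Build a code-entry table
#'
#' @param code_id Character vector of code identifiers (always text; leading
#'   characters are preserved and ids are never parsed as numbers).
#' @param term Human-readable code descriptions.
#' @param ontology Ontology tag per code: one of `"SNOMED"`, `"READ_V2"`,
#'   `"CTV3"`, `"MEDCODE"`, `"DMD"`.
#' @param provenance Source labels per code, either a character vector or a
#'   list of character vectors; stored as a sorted `";"`-joined label set.
#' @param status Validation status per code (`"draft"`, `"needs_review"`,
#'   `"auto_validated"`, `"approved"`, `"excluded"`).
#' @param boundary_case 0/1 flag: 1 marks a boundary code (suggestive but not
#'   exclusive of the condition) requiring two-reviewer adjudication.
#' @return A tibble with columns `ontology`, `code_id`, `term`, `provenance`,
#'   `status`, `boundary_case`.
#' @export
code_entries <- function(code_id, term, ontology = "SNOMED",
                         provenance = "", status = "draft",
                         boundary_case = 0L) {
  n <- length(code_id)
  if (is.list(provenance)) {
    provenance <- vapply(provenance, prov_join, character(1))
  }
  tb <- tibble::tibble(
    ontology = rep_len(as.character(ontology), n),
    code_id = as.character(code_id),
    term = rep_len(as.character(term), n),
    provenance = rep_len(as.character(provenance), n),
    status = rep_len(as.character(status), n),
    boundary_case = rep_len(as.integer(boundary_case), n)
  )
  check_entries(tb)
  tb
}

prov_join <- function(labels) {
  labels <- unique(labels[nzchar(labels)])
  paste(sort(labels), collapse = ";")
}

prov_split <- function(x) {
  strsplit(x, ";", fixed = TRUE)
}

prov_union <- function(a, b) {
  mapply(function(x, y) prov_join(c(x, y)), prov_split(a), prov_split(b))
}

merge_status <- function(a, b) {
  ifelse(a == "excluded" | b == "excluded", "excluded",
    ifelse(.status_rank[a] >= .status_rank[b], a, b)
  )
}

check_entries <- function(entries) {
  missing <- setdiff(ENTRY_COLS, names(entries))
  if (length(missing)) {
    stop_format(paste0("Entry table is missing column(s): ", toString(missing)))
  }
  bad_ont <- setdiff(unique(entries$ontology), ONTOLOGIES)
  if (length(bad_ont)) {
    stop_format(paste0("Unknown ontology tag(s): ", toString(bad_ont)))
  }
  bad_status <- setdiff(unique(entries$status), STATUSES)
  if (length(bad_status)) {
    stop_format(paste0("Unknown status value(s): ", toString(bad_status)))
  }
  if (any(is.na(entries$code_id) | !nzchar(entries$code_id) |
    grepl("[[:space:]]", entries$code_id))) {
    stop_invalid("code_id must be non-empty and contain no whitespace.")
  }
  snomed <- entries$ontology == "SNOMED"
  if (any(snomed) && !all(validate_sctid(entries$code_id[snomed]))) {
    bad <- entries$code_id[snomed][!validate_sctid(entries$code_id[snomed])]
    stop_invalid(paste0(
      "Invalid SNOMED identifier(s) (must be digits-only, length 6-18): ",
      toString(utils::head(bad, 5))
    ))
  }
  if (!all(entries$boundary_case %in% c(0L, 1L))) {
    stop_invalid("boundary_case must be 0 or 1.")
  }
  invisible(entries)
}

sort_entries <- function(entries) {
  entries[order(entries$ontology, entries$code_id), , drop = FALSE]
}

# Collapse duplicate (ontology, code_id) rows: provenance sets are unioned,
# statuses merged on the validation lattice, boundary flags OR-ed, first
# non-empty term kept.
dedupe_entries <- function(entries) {
  if (nrow(entries) < 2L) return(sort_entries(entries))
  key <- paste(entries$ontology, entries$code_id, sep = "\r")
  groups <- split(seq_len(nrow(entries)), key)
  rows <- lapply(groups, function(idx) {
    e <- entries[idx, , drop = FALSE]
    status <- Reduce(merge_status, e$status)
    term <- e$term[nzchar(e$term)][1]
    if (is.na(term)) term <- e$term[1]
    tibble::tibble(
      ontology = e$ontology[1], code_id = e$code_id[1], term = term,
      provenance = prov_join(unlist(prov_split(e$provenance))),
      status = status, boundary_case = max(e$boundary_case)
    )
  })
  sort_entries(dplyr::bind_rows(rows))
}

#' Create a codelist
#'
#' @param condition_name Display name of the clinical concept.
#' @param entries A code-entry tibble, see [code_entries()].
#' @param plural_exceptions Passed to [normalize_condition_name()].
#' @return A `codelist` object: condition name, canonical key, and a
#'   deduplicated entry table keyed by (ontology, code_id).
#' @examples
#' codelist("Asthma", code_entries(
#'   c("195967001", "281239006"),
#'   c("Asthma", "Exacerbation of asthma")
#' ))
#' @export
codelist <- function(condition_name, entries = code_entries(character(0), character(0)),
                     plural_exceptions = plural_exception_terms()) {
  check_entries(entries)
  structure(
    list(
      condition_name = condition_name,
      canonical_key = normalize_condition_name(condition_name, plural_exceptions),
      entries = dedupe_entries(entries)
    ),
    class = "codelist"
  )
}

#' @export
print.codelist <- function(x, ...) {
  cat(sprintf(
    "<codelist> %s [%s] - %d code(s)\n",
    x$condition_name, x$canonical_key, nrow(x$entries)
  ))
  print(x$entries, n = 10)
  invisible(x)
}

#' Accessors for codelist objects
#'
#' @param x A `codelist`.
#' @return `condition_name()` and `canonical_key()` return strings,
#'   `entries()` the entry tibble, `n_codes()` the number of entries.
#' @export
condition_name <- function(x) UseMethod("condition_name")
#' @export
condition_name.codelist <- function(x) x$condition_name

#' @rdname condition_name
#' @export
canonical_key <- function(x) UseMethod("canonical_key")
#' @export
canonical_key.codelist <- function(x) x$canonical_key

#' @rdname condition_name
#' @export
entries <- function(x) UseMethod("entries")
#' @export
entries.codelist <- function(x) x$entries

#' @rdname condition_name
#' @export
n_codes <- function(x) UseMethod("n_codes")
#' @export
n_codes.codelist <- function(x) nrow(x$entries)

#' Merge codelists into one
#'
#' Union by (ontology, code_id): provenance sets are unioned per shared entry;
#' the merged status is the most validated of the inputs (approved >
#' auto_validated > needs_review > draft) except that `excluded` is sticky and
#' wins over all; boundary flags are OR-ed.
#'
#' @param ... One or more `codelist` objects (or a single list of them).
#' @param merged_name Display name of the merged codelist.
#' @return A `codelist`.
#' @export
merge_codelists <- function(..., merged_name) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1]], "codelist")) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0L) {
    stop_invalid("merge_codelists() needs at least one codelist.")
  }
  ok <- vapply(lists, inherits, logical(1), what = "codelist")
  if (!all(ok)) stop_invalid("All inputs to merge_codelists() must be codelists.")
  codelist(merged_name, dplyr::bind_rows(lapply(lists, entries)))
}

#' Create a codelist collection
#'
#' A keyed set of codelists from one source; keys are the canonical condition
#' keys.
#'
#' @param lists A list of `codelist` objects.
#' @param source_label Label of the originating source (baseline or trusted
#'   list release).
#' @return A `codelist_collection`.
#' @export
codelist_collection <- function(lists = list(), source_label = "unnamed") {
  keys <- vapply(lists, canonical_key, character(1))
  if (anyDuplicated(keys)) {
    stop_invalid(paste0(
      "Duplicate canonical keys in collection: ",
      toString(unique(keys[duplicated(keys)]))
    ))
  }
  names(lists) <- keys
  structure(
    list(source_label = source_label, lists = lists[order(keys)]),
    class = "codelist_collection"
  )
}

#' @export
print.codelist_collection <- function(x, ...) {
  cat(sprintf(
    "<codelist_collection> '%s': %d condition(s), %d code(s)\n",
    x$source_label, length(x$lists),
    sum(vapply(x$lists, n_codes, integer(1)))
  ))
  for (key in utils::head(names(x$lists), 12)) {
    cat(sprintf("  %-40s %d code(s)\n", key, n_codes(x$lists[[key]])))
  }
  if (length(x$lists) > 12) cat(sprintf("  ... and %d more\n", length(x$lists) - 12))
  invisible(x)
}

#' @rdname condition_name
#' @export
source_label <- function(x) UseMethod("source_label")
#' @export
source_label.codelist_collection <- function(x) x$source_label

#' @export
length.codelist_collection <- function(x) length(x$lists)

#' @export
names.codelist_collection <- function(x) names(x$lists)

#' @export
`[[.codelist_collection` <- function(x, i) x$lists[[i]]

#' Collection manipulation helpers
#'
#' @param collection A `codelist_collection`.
#' @param x A `codelist` to add (replaces any list with the same key).
#' @param keys Canonical keys to drop.
#' @return The modified collection.
#' @export
collection_add <- function(collection, x) {
  stopifnot(inherits(collection, "codelist_collection"), inherits(x, "codelist"))
  lists <- collection$lists
  lists[[canonical_key(x)]] <- x
  codelist_collection(unname(lists), collection$source_label)
}

#' @rdname collection_add
#' @export
collection_drop <- function(collection, keys) {
  stopifnot(inherits(collection, "codelist_collection"))
  lists <- collection$lists[setdiff(names(collection$lists), keys)]
  codelist_collection(unname(lists), collection$source_label)
}

#' Total code count of a collection
#'
#' @param collection A `codelist_collection`.
#' @return Integer: sum of per-condition entry counts (a code appearing under
#'   two conditions counts once per condition).
#' @export
total_codes <- function(collection) {
  sum(vapply(collection$lists, n_codes, integer(1)))
}
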