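# Shrinking: automatic validation of draft codes against a trusted,
# previously clinically validated source (e.g. the CALIBER phenotype
# library). A draft code found in the condition's mapped trusted lists is
# marked auto_validated and needs no clinician time; the remainder are marked
# needs_review. Shrinking changes statuses only - no code is ever removed
# from the record. Matching is by SNOMED id alone: terms vary across
# terminology releases, the identifier is the identity.

#' Build a trusted-source map in code
#'
#' @param ... Named arguments: `condition = c("trusted list", ...)`. Names and
#'   list names are normalised to canonical keys.
#' @param trusted Optional trusted `codelist_collection` to validate against.
#' @return A `trusted_source_map`.
#' @export
trusted_source_map <- function(..., trusted = NULL) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) && is.null(names(entries))) {
    entries <- entries[[1]]
  }
  if (length(entries) == 0L) {
    tmap <- structure(list(), class = "trusted_source_map")
    return(tmap)
  }
  tmap <- lapply(entries, normalize_condition_name)
  names(tmap) <- normalize_condition_name(names(entries))
  tmap <- structure(tmap, class = "trusted_source_map")
  if (!is.null(trusted)) validate_trusted_map(tmap, trusted)
  tmap
}

#' Resolve the trusted code set for a condition
#'
#' Union of SNOMED ids across all trusted lists mapped to the condition. An
#' unmapped condition yields the empty set: it is "newly introduced" and its
#' whole codelist requires clinical review.
#'
#' @param key Canonical condition key.
#' @param tmap A `trusted_source_map`.
#' @param trusted Trusted `codelist_collection`.
#' @return Character vector of SNOMED code ids (possibly empty).
#' @export
resolve_trusted_codes <- function(key, tmap, trusted) {
  list_keys <- tmap[[key]]
  if (is.null(list_keys)) return(character(0))
  missing <- setdiff(list_keys, names(trusted))
  if (length(missing)) {
    stop_config(paste0(
      "Condition '", key, "' is mapped to missing trusted list(s): ",
      toString(missing)
    ))
  }
  sort(unique(unlist(lapply(list_keys, function(k) entries(trusted[[k]])$code_id))))
}

#' Shrink one draft codelist against a trusted code set
#'
#' @param draft A non-empty, all-SNOMED draft `codelist`.
#' @param trusted_codes Character vector of trusted SNOMED ids.
#' @return A list with `codelist` (statuses updated: `auto_validated` when the
#'   id is trusted, `needs_review` otherwise; prior `approved`/`excluded`
#'   review outcomes are preserved) and `row`, a one-row tibble
#'   (`canonical_key`, `n_draft`, `n_auto_validated`, `n_remaining`,
#'   `shrink_pct` with two decimal places).
#' @examples
#' d <- codelist("Asthma", code_entries(
#'   c("195967001", "281239006", "233678006"),
#'   c("Asthma", "Exacerbation of asthma", "Childhood asthma")
#' ))
#' shrink_codelist(d, c("195967001", "281239006"))$row
#' @export
shrink_codelist <- function(draft, trusted_codes) {
  stopifnot(inherits(draft, "codelist"))
  e <- entries(draft)
  if (nrow(e) == 0L) {
    stop_invalid(paste0(
      "Cannot shrink empty codelist '", canonical_key(draft),
      "': shrink percentage is undefined."
    ))
  }
  if (!all(e$ontology == "SNOMED")) {
    stop_invalid("Shrinking requires an all-SNOMED codelist; map legacy codes first.")
  }
  matched <- e$code_id %in% trusted_codes
  keep_prior <- e$status %in% c("approved", "excluded")
  e$status[!keep_prior] <- ifelse(matched[!keep_prior], "auto_validated", "needs_review")
  n_draft <- nrow(e)
  n_auto <- sum(matched)
  row <- tibble::tibble(
    canonical_key = canonical_key(draft),
    n_draft = n_draft,
    n_auto_validated = n_auto,
    n_remaining = n_draft - n_auto,
    shrink_pct = round(100 * n_auto / n_draft, 2)
  )
  list(codelist = codelist(condition_name(draft), e), row = row)
}

#' Shrink a whole draft collection
#'
#' Applies [shrink_codelist()] per condition with the trusted code set
#' resolved through the trusted-source map, and assembles the workload-
#' reduction report.
#'
#' @param drafts An all-SNOMED draft `codelist_collection`.
#' @param tmap A `trusted_source_map`.
#' @param trusted Trusted `codelist_collection`.
#' @return A list with `collection` (statuses updated) and `report`, a
#'   `shrink_report`: `rows` (per-condition, sorted by canonical key),
#'   `overall_pct` (code-weighted: `100 * sum(n_auto) / sum(n_draft)`),
#'   `macro_pct` (unweighted mean of row percentages, emitted for
#'   transparency), and `duplicates` (codes appearing under more than one
#'   condition - flagged, never deleted).
#' @export
shrink_collection <- function(drafts, tmap, trusted) {
  stopifnot(inherits(drafts, "codelist_collection"))
  validate_trusted_map(tmap, trusted)
  keys <- sort(names(drafts))
  shrunk <- vector("list", length(keys))
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    res <- shrink_codelist(
      drafts[[keys[i]]],
      resolve_trusted_codes(keys[i], tmap, trusted)
    )
    shrunk[[i]] <- res$codelist
    rows[[i]] <- res$row
  }
  rows <- dplyr::bind_rows(rows)
  report <- structure(
    list(
      rows = rows,
      overall_pct = round(100 * sum(rows$n_auto_validated) / sum(rows$n_draft), 2),
      macro_pct = round(mean(rows$shrink_pct), 2),
      duplicates = cross_condition_duplicates(drafts)
    ),
    class = "shrink_report"
  )
  list(
    collection = codelist_collection(shrunk, drafts$source_label),
    report = report
  )
}

# Codes present in more than one condition's list. The record keeps them in
# every condition; the report surfaces them for human attention.
cross_condition_duplicates <- function(collection) {
  rows <- dplyr::bind_rows(lapply(names(collection), function(key) {
    tibble::tibble(code_id = unique(entries(collection[[key]])$code_id), condition = key)
  }))
  if (nrow(rows) == 0L) {
    return(tibble::tibble(code_id = character(0), conditions = list()))
  }
  dup <- dplyr::summarise(dplyr::group_by(rows, .data$code_id),
    conditions = list(sort(.data$condition)), n = dplyr::n()
  )
  dup <- dup[dup$n > 1L, c("code_id", "conditions")]
  dup[order(dup$code_id), , drop = FALSE]
}

#' @export
print.shrink_report <- function(x, ...) {
  cat(sprintf(
    "<shrink_report> %d condition(s), %d code(s): %d auto-validated (%.2f%% overall, %.2f%% macro), %d left for review\n",
    nrow(x$rows), sum(x$rows$n_draft), sum(x$rows$n_auto_validated),
    x$overall_pct, x$macro_pct, sum(x$rows$n_remaining)
  ))
  print(x$rows, n = 10)
  invisible(x)
}

#' Write a shrink report as CSV
#'
#' Per-condition rows plus a final `__overall__` summary record carrying the
#' code-weighted overall percentage.
#'
#' @param report A `shrink_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shrink_report_csv <- function(report, path) {
  rows <- report$rows
  overall <- tibble::tibble(
    canonical_key = "__overall__",
    n_draft = sum(rows$n_draft),
    n_auto_validated = sum(rows$n_auto_validated),
    n_remaining = sum(rows$n_remaining),
    shrink_pct = report$overall_pct
  )
  readr::write_csv(dplyr::bind_rows(rows, overall), path, progress = FALSE)
  invisible(path)
}
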