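# Summary artefacts: cross-source comparison counts, new codes added over the
# trusted source, and size-bucket profiles of condition list sizes.

#' Compare collections by condition and code counts
#'
#' One row per collection: number of conditions, total codes (unique
#' (ontology, code) pairs per condition; a code under two conditions counts
#' once per condition), and the same two counts restricted to a filter subset
#' of conditions (e.g. the conditions regarded as long-term for
#' multimorbidity work). With no filter the restricted counts equal the full
#' ones.
#'
#' @param collections A list of `codelist_collection`s.
#' @param mltc_filter Optional character vector of condition names (or
#'   canonical keys) defining the restricted subset.
#' @return A tibble: `source_label`, `n_conditions`, `n_codes`,
#'   `n_conditions_mltc`, `n_codes_mltc`.
#' @export
comparison_table <- function(collections, mltc_filter = NULL) {
  if (inherits(collections, "codelist_collection")) collections <- list(collections)
  filter_keys <- if (!is.null(mltc_filter)) normalize_condition_name(mltc_filter)
  rows <- lapply(collections, function(coll) {
    sizes <- vapply(coll$lists, n_codes, integer(1))
    in_filter <- if (is.null(filter_keys)) {
      rep(TRUE, length(sizes))
    } else {
      names(coll$lists) %in% filter_keys
    }
    tibble::tibble(
      source_label = coll$source_label,
      n_conditions = length(sizes),
      n_codes = sum(sizes),
      n_conditions_mltc = sum(in_filter),
      n_codes_mltc = sum(sizes[in_filter])
    )
  })
  dplyr::bind_rows(rows)
}

#' Count new codes relative to the trusted source
#'
#' For each condition of the final (validated) collection, the number of
#' included codes (status `approved` or `auto_validated`) absent from its
#' resolved trusted code set. Conditions unmapped in the trusted-source map
#' contribute all their included codes as new. All conditions are returned,
#' including zero-new ones; display tables typically omit the zeros
#' (`omit_zero = TRUE`).
#'
#' @param final A validated `codelist_collection`.
#' @param tmap A `trusted_source_map`.
#' @param trusted Trusted `codelist_collection`.
#' @param omit_zero Drop conditions with no new codes?
#' @return A tibble: `canonical_key`, `condition`, `n_included`, `n_new`.
#' @export
new_codes_vs_trusted <- function(final, tmap, trusted, omit_zero = FALSE) {
  stopifnot(inherits(final, "codelist_collection"))
  validate_trusted_map(tmap, trusted)
  rows <- lapply(sort(names(final)), function(key) {
    cl <- final[[key]]
    e <- entries(cl)
    included <- e$code_id[e$status %in% c("approved", "auto_validated")]
    trusted_ids <- resolve_trusted_codes(key, tmap, trusted)
    tibble::tibble(
      canonical_key = key,
      condition = condition_name(cl),
      n_included = length(included),
      n_new = length(setdiff(included, trusted_ids))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (omit_zero) out <- out[out$n_new > 0L, , drop = FALSE]
  out
}

#' Default size buckets for condition profiles
#'
#' Bucket edges for summarising how many codes conditions contain, following
#' the narrative bands commonly reported for long-term-condition codelists
#' (a few codes, around ten, around twenty, tens, and the large 80+ lists).
#'
#' @return A tibble with columns `min`, `max` (inclusive).
#' @export
default_size_buckets <- function() {
  tibble::tibble(
    min = c(1L, 11L, 16L, 30L, 80L),
    max = c(10L, 15L, 29L, 79L, .Machine$integer.max)
  )
}

#' Profile condition sizes into buckets
#'
#' @param collection A `codelist_collection`.
#' @param buckets A tibble with inclusive `min`/`max` columns; buckets must
#'   not overlap and every condition size must fall in exactly one bucket.
#' @return A tibble: `bucket` (label), `min`, `max`, `n_conditions`; counts
#'   sum to the number of conditions.
#' @export
size_profile <- function(collection, buckets = default_size_buckets()) {
  if (!all(c("min", "max") %in% names(buckets))) {
    stop_config("`buckets` needs `min` and `max` columns.")
  }
  if (any(buckets$min > buckets$max)) {
    stop_config("Each bucket needs min <= max.")
  }
  b <- buckets[order(buckets$min), , drop = FALSE]
  if (nrow(b) > 1L && any(b$min[-1] <= b$max[-nrow(b)])) {
    stop_config("Size buckets overlap.")
  }
  sizes <- vapply(collection$lists, n_codes, integer(1))
  counts <- vapply(seq_len(nrow(b)), function(i) {
    sum(sizes >= b$min[i] & sizes <= b$max[i])
  }, integer(1))
  uncovered <- sizes[!vapply(sizes, function(s) any(s >= b$min & s <= b$max), logical(1))]
  if (length(uncovered)) {
    stop_config(paste0(
      "Condition size(s) not covered by any bucket: ", toString(unique(uncovered))
    ))
  }
  tibble::tibble(
    bucket = paste0(
      b$min, "-", ifelse(b$max == .Machine$integer.max, "up", b$max)
    ),
    min = b$min, max = b$max, n_conditions = counts
  )
}

#' One-line plain-text workload summary
#'
#' @param report A `shrink_report`.
#' @return A string such as "automation validated 84.20% of codes, leaving
#'   158 for review".
#' @export
summary_sentence <- function(report) {
  sprintf(
    "automation validated %.2f%% of codes, leaving %d for review",
    report$overall_pct, sum(report$rows$n_remaining)
  )
}
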