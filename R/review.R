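# Residual clinical review: trigger criteria deciding whether a codelist
# needs clinician review at all, boundary-code adjudication (two reviewers,
# third casting vote on disagreement), review-sheet export/import, and an
# append-only audit log of every decision.

REVIEW_CRITERIA <- c(
  "subset_of_verified_unreviewed",
  "combination_of_verified_unreviewed",
  "no_published_codelist",
  "involves_test_codes"
)

#' Decide whether a codelist needs clinical review
#'
#' A codelist needs review by at least two clinicians when any of the four
#' criteria hold: (1) it is a subset of a previously verified codelist but
#' has not itself been reviewed, (2) it is a combination of previously
#' verified codelists not reviewed in this form, (3) it is for a condition
#' without any existing published codelist, or (4) it involves test codes
#' (e.g. diagnoses made from a biomarker). When only the test-code criterion
#' fires, only the test codes need review (`scope = "test_codes"`); when no
#' criterion fires the list may be used as published and the source is
#' logged.
#'
#' @param subset_of_verified_unreviewed,combination_of_verified_unreviewed,no_published_codelist,involves_test_codes
#'   Logical criterion flags, computable from codelist metadata.
#' @param published_source Label of the published source; logged when no
#'   review is needed.
#' @return A list: `needs_review` (logical), `triggered` (names of the
#'   criteria that fired), `scope` (`"none"`, `"all"` or `"test_codes"`), and
#'   `logged_source` (the published source when no review is needed, else
#'   `NA`).
#' @export
classify_review_need <- function(subset_of_verified_unreviewed = FALSE,
                                 combination_of_verified_unreviewed = FALSE,
                                 no_published_codelist = FALSE,
                                 involves_test_codes = FALSE,
                                 published_source = NULL) {
  flags <- c(
    subset_of_verified_unreviewed, combination_of_verified_unreviewed,
    no_published_codelist, involves_test_codes
  )
  triggered <- REVIEW_CRITERIA[flags]
  needs <- any(flags)
  scope <- if (!needs) {
    "none"
  } else if (identical(triggered, "involves_test_codes")) {
    "test_codes"
  } else {
    "all"
  }
  list(
    needs_review = needs,
    triggered = triggered,
    scope = scope,
    logged_source = if (!needs && !is.null(published_source)) published_source else NA_character_
  )
}

#' Adjudicate a boundary code
#'
#' Boundary codes are reviewed by two clinicians; two concordant votes decide
#' the outcome, a 1-1 split stays `pending` until a third casting vote, and
#' with three (or more) votes the majority decides.
#'
#' @param votes Character vector of `"include"`/`"exclude"` votes, in voting
#'   order.
#' @param reviewers Optional reviewer identifiers (one per vote); two votes
#'   from the same reviewer are an error.
#' @return `"include"`, `"exclude"` or `"pending"`.
#' @examples
#' adjudicate_boundary(c("include", "include"))
#' adjudicate_boundary(c("include", "exclude"))
#' adjudicate_boundary(c("include", "exclude", "exclude"))
#' @export
adjudicate_boundary <- function(votes, reviewers = NULL) {
  if (length(votes) == 0L) {
    stop_invalid("At least one vote is required.")
  }
  if (!all(votes %in% c("include", "exclude"))) {
    stop_invalid("Votes must be 'include' or 'exclude'.")
  }
  if (!is.null(reviewers)) {
    if (length(reviewers) != length(votes)) {
      stop_invalid("`reviewers` must be one identifier per vote.")
    }
    if (anyDuplicated(reviewers)) {
      stop_reconciliation(paste0(
        "Duplicate reviewer vote(s) from: ",
        toString(unique(reviewers[duplicated(reviewers)]))
      ))
    }
  }
  n_inc <- sum(votes == "include")
  n_exc <- sum(votes == "exclude")
  if (length(votes) == 1L || n_inc == n_exc) return("pending")
  if (n_inc > n_exc) "include" else "exclude"
}

REVIEW_SHEET_COLS <- c(
  "condition", "code", "term", "Boundary_case",
  "reviewer_1", "reviewer_2", "reviewer_3", "outcome", "note"
)

#' Export the clinical review sheet
#'
#' Emits only entries with status `needs_review`, grouped by condition, with
#' the `Boundary_case` column and empty reviewer/outcome/note columns for the
#' panel to fill in. Per-condition row counts equal the shrink report's
#' `n_remaining`.
#'
#' @param collection A shrunk `codelist_collection`.
#' @param path Optional CSV path; when given the sheet is written there.
#' @return The review-sheet tibble (invisibly when `path` is given).
#' @export
export_review_sheet <- function(collection, path = NULL) {
  stopifnot(inherits(collection, "codelist_collection"))
  rows <- lapply(sort(names(collection)), function(key) {
    cl <- collection[[key]]
    e <- sort_entries(entries(cl))
    e <- e[e$status == "needs_review", , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    tibble::tibble(
      condition = rep(condition_name(cl), nrow(e)),
      code = e$code_id, term = e$term, Boundary_case = e$boundary_case,
      reviewer_1 = "", reviewer_2 = "", reviewer_3 = "",
      outcome = "", note = ""
    )
  })
  sheet <- dplyr::bind_rows(rows)
  if (nrow(sheet) == 0L) {
    sheet <- tibble::as_tibble(stats::setNames(
      c(
        rep(list(character(0)), 3), list(integer(0)),
        rep(list(character(0)), 5)
      ),
      REVIEW_SHEET_COLS
    ))
  }
  if (!is.null(path)) {
    readr::write_csv(sheet, path, progress = FALSE)
    return(invisible(sheet))
  }
  sheet
}

read_review_sheet <- function(path) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("condition", "code"), path)
  for (col in setdiff(REVIEW_SHEET_COLS, names(df))) df[[col]] <- ""
  df$Boundary_case[!nzchar(df$Boundary_case)] <- "0"
  df[REVIEW_SHEET_COLS]
}

row_votes <- function(sheet_row) {
  v <- tolower(trimws(c(
    sheet_row$reviewer_1, sheet_row$reviewer_2, sheet_row$reviewer_3
  )))
  v[nzchar(v)]
}

decide_row <- function(sheet_row) {
  votes <- row_votes(sheet_row)
  stated <- tolower(trimws(sheet_row$outcome))
  boundary <- as.integer(sheet_row$Boundary_case) == 1L
  decided <- if (length(votes)) adjudicate_boundary(votes) else "pending"
  if (nzchar(stated)) {
    if (!stated %in% c("include", "exclude", "pending")) {
      stop_reconciliation(paste0(
        "Unknown outcome '", sheet_row$outcome, "' for code ", sheet_row$code, "."
      ))
    }
    if (length(votes) && decided != "pending" && stated != decided) {
      stop_reconciliation(paste0(
        "Outcome '", stated, "' contradicts the recorded votes (",
        paste(votes, collapse = "/"), ") for code ", sheet_row$code, "."
      ))
    }
    if (boundary && stated != "pending" && length(votes) < 2L) {
      stop_reconciliation(paste0(
        "Boundary code ", sheet_row$code,
        " has outcome '", stated, "' without the two recorded reviewer votes."
      ))
    }
    if (boundary && decided == "pending" && length(votes) >= 2L && stated != "pending") {
      stop_reconciliation(paste0(
        "Boundary code ", sheet_row$code,
        " has a 1-1 reviewer split; a third casting vote is required before '",
        stated, "'."
      ))
    }
    return(stated)
  }
  if (boundary && decided != "pending" && length(votes) < 2L) return("pending")
  decided
}

#' Import completed review decisions
#'
#' Applies a filled-in review sheet: `include` outcomes set status
#' `approved`, `exclude` set `excluded` (excluded boundary codes stay in the
#' record - exclusion is a recorded decision, not a deletion), `pending` rows
#' leave the status at `needs_review`. Every status change is appended to an
#' immutable audit log (who voted, what changed, when, note). Unknown
#' (condition, code) references and conflicting duplicate rows are
#' reconciliation errors.
#'
#' @param sheet A review-sheet tibble or CSV path (see
#'   [export_review_sheet()]).
#' @param collection The `codelist_collection` the sheet was exported from.
#' @param audit_path Optional path of the append-only audit-log CSV; created
#'   with a header on first use, appended to afterwards.
#' @param now Timestamp recorded in the audit log (injectable for
#'   reproducible runs).
#' @return A list with `collection` (statuses updated) and `audit` (tibble of
#'   the audit records appended by this call).
#' @export
import_review_decisions <- function(sheet, collection, audit_path = NULL,
                                    now = Sys.time()) {
  if (is.character(sheet)) sheet <- read_review_sheet(sheet)
  stopifnot(inherits(collection, "codelist_collection"))
  if (nrow(sheet)) {
    sheet_key <- normalize_condition_name(sheet$condition)
  } else {
    sheet_key <- character(0)
  }

  ref <- paste(sheet_key, sheet$code, sep = "\r")
  if (anyDuplicated(ref)) {
    dup <- unique(ref[duplicated(ref)])
    conflicting <- vapply(dup, function(r) {
      rows <- sheet[ref == r, , drop = FALSE]
      length(unique(tolower(trimws(rows$outcome)))) > 1L ||
        nrow(unique(rows[c("reviewer_1", "reviewer_2", "reviewer_3")])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop_reconciliation(paste0(
        "Conflicting duplicate review rows for code(s): ",
        toString(sub("^.*\r", "", dup[conflicting]))
      ))
    }
    keep <- !duplicated(ref)
    sheet <- sheet[keep, , drop = FALSE]
    sheet_key <- sheet_key[keep]
    ref <- ref[keep]
  }

  unknown <- character(0)
  audit <- list()
  lists <- collection$lists
  for (i in seq_len(nrow(sheet))) {
    cl <- lists[[sheet_key[i]]]
    if (is.null(cl)) {
      unknown <- c(unknown, paste0(sheet_key[i], "/", sheet$code[i]))
      next
    }
    e <- cl$entries
    j <- which(e$code_id == sheet$code[i])
    if (length(j) == 0L) {
      unknown <- c(unknown, paste0(sheet_key[i], "/", sheet$code[i]))
      next
    }
    outcome <- decide_row(sheet[i, , drop = FALSE])
    new_status <- switch(outcome,
      include = "approved",
      exclude = "excluded",
      pending = e$status[j]
    )
    if (!identical(new_status, e$status[j])) {
      audit[[length(audit) + 1L]] <- tibble::tibble(
        timestamp = format(now, "%Y-%m-%dT%H:%M:%S%z"),
        condition = sheet_key[i],
        code_id = sheet$code[i],
        old_status = e$status[j],
        new_status = new_status,
        outcome = outcome,
        votes = paste(row_votes(sheet[i, , drop = FALSE]), collapse = ";"),
        note = sheet$note[i]
      )
      e$status[j] <- new_status
      lists[[sheet_key[i]]] <- codelist(condition_name(cl), e)
    }
  }
  if (length(unknown)) {
    stop_reconciliation(paste0(
      "Review sheet references unknown (condition, code) pair(s): ",
      toString(unknown)
    ))
  }
  audit <- if (length(audit)) {
    dplyr::bind_rows(audit)
  } else {
    tibble::tibble(
      timestamp = character(0), condition = character(0),
      code_id = character(0), old_status = character(0),
      new_status = character(0), outcome = character(0),
      votes = character(0), note = character(0)
    )
  }
  if (!is.null(audit_path) && nrow(audit)) {
    readr::write_csv(audit, audit_path,
      append = file.exists(audit_path), progress = FALSE
    )
  }
  list(
    collection = codelist_collection(unname(lists), collection$source_label),
    audit = audit
  )
}
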