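# External file contracts. All tables are UTF-8 delimited text; the codelist
# CSV is the interchange format every pipeline stage reads and writes. Writers
# emit rows sorted by (canonical_key, ontology, code_id) so repeated runs are
# byte-stable.

CODELIST_COLS <- c("condition", "code", "term", "ontology", "source", "status", "Boundary_case")

read_delim_quiet <- function(path, col_types) {
  if (!file.exists(path)) {
    stop_format(paste0("File not found: ", path))
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path,
    delim = delim, col_types = col_types,
    na = character(0), progress = FALSE, show_col_types = FALSE
  )
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_format(paste0(
      "File '", path, "' is missing mandatory column(s): ", toString(missing)
    ))
  }
  invisible(df)
}

#' Read a codelist CSV into a collection
#'
#' Expected columns: `condition`, `code`, `term`, `ontology`, `source`,
#' `status`, `Boundary_case`. The reader tolerates a missing `status`
#' (defaults `draft`), `Boundary_case` (defaults 0), `ontology` (defaults
#' `SNOMED`) and `source` (defaults to `source_label`); the writer always
#' emits all columns. `Boundary_case` is 1 for boundary codes, matching the
#' published codelist CSV contract.
#'
#' @param path CSV (or TSV) file path.
#' @param source_label Label for the collection; defaults to the file name.
#' @return A `codelist_collection` with one codelist per distinct condition.
#' @export
read_codelist_csv <- function(path, source_label = NULL) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("condition", "code", "term"), path)
  if (is.null(source_label)) {
    source_label <- sub("\\.[^.]+$", "", basename(path))
  }
  if (is.null(df[["ontology"]])) df$ontology <- "SNOMED"
  if (is.null(df[["source"]]) || all(!nzchar(df$source))) df$source <- source_label
  if (is.null(df[["status"]])) df$status <- "draft"
  if (is.null(df[["Boundary_case"]])) df$Boundary_case <- "0"
  df$status[!nzchar(df$status)] <- "draft"
  df$Boundary_case[!nzchar(df$Boundary_case)] <- "0"

  lists <- lapply(split(df, df$condition), function(d) {
    codelist(d$condition[1], code_entries(
      code_id = d$code, term = d$term, ontology = d$ontology,
      provenance = prov_split(d$source), status = d$status,
      boundary_case = as.integer(d$Boundary_case)
    ))
  })
  codelist_collection(unname(lists), source_label)
}

collection_to_frame <- function(collection) {
  keys <- sort(names(collection$lists))
  rows <- lapply(keys, function(key) {
    cl <- collection$lists[[key]]
    e <- sort_entries(cl$entries)
    tibble::tibble(
      condition = rep(cl$condition_name, nrow(e)),
      code = e$code_id, term = e$term, ontology = e$ontology,
      source = e$provenance, status = e$status,
      Boundary_case = e$boundary_case
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      condition = character(0), code = character(0), term = character(0),
      ontology = character(0), source = character(0), status = character(0),
      Boundary_case = integer(0)
    )
  }
  out
}

#' Write a collection to the codelist CSV format
#'
#' Rows sorted by (canonical key, ontology, code) for byte-stable output.
#'
#' @param collection A `codelist_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codelist_csv <- function(collection, path) {
  readr::write_csv(collection_to_frame(collection), path, progress = FALSE)
  invisible(path)
}

split_field <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

#' Read a clinician directive table
#'
#' Expected columns: `condition`, `action` (`keep`/`group`/`split`),
#' `merged_name` (group only), `split_targets` (semicolon-separated, split
#' only), `related_terms` (semicolon-separated), `comment`. Missing optional
#' columns default to empty.
#'
#' @param path Delimited file path.
#' @return A `condition_directives` tibble (see [condition_directive()]).
#' @export
read_directives_csv <- function(path) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("condition", "action"), path)
  for (col in c("merged_name", "split_targets", "related_terms", "comment")) {
    if (is.null(df[[col]])) df[[col]] <- ""
  }
  dirs <- lapply(seq_len(nrow(df)), function(i) {
    targets <- if (df$action[i] == "group") {
      tg <- trimws(df$merged_name[i])
      tg[nzchar(tg)]
    } else {
      split_field(df$split_targets[i])[[1]]
    }
    condition_directive(
      condition = df$condition[i], action = df$action[i],
      related_terms = split_field(df$related_terms[i])[[1]],
      targets = targets, comment = df$comment[i]
    )
  })
  dplyr::bind_rows(dirs)
}

#' Read a split-rule table
#'
#' Expected columns: `condition`, `target`, `keywords` (semicolon-separated),
#' `priority` (integer rank, 1 = highest).
#'
#' @param path Delimited file path.
#' @return A tibble with one row per rule, keywords as a list-column.
#' @export
read_split_rules_csv <- function(path) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("condition", "target", "keywords", "priority"), path)
  tibble::tibble(
    condition = df$condition,
    target = df$target,
    keywords = split_field(df$keywords),
    priority = as.integer(df$priority)
  )
}

#' Read a trusted-source map
#'
#' Maps project condition names to the trusted lists they are validated
#' against (e.g. "Bladder Dysfunction" to the CALIBER lists
#' "kuan neuro bladder" and "kuan pri bladder"). Expected columns:
#' `condition`, `trusted_list_names` (semicolon-separated).
#'
#' @param path Delimited file path.
#' @param trusted Optional `codelist_collection` of trusted lists; when given,
#'   every referenced list name must resolve in it (configuration error
#'   otherwise).
#' @return A `trusted_source_map`: named list, canonical condition key ->
#'   character vector of trusted-list canonical keys.
#' @export
read_trusted_map_csv <- function(path, trusted = NULL) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("condition", "trusted_list_names"), path)
  tmap <- split_field(df$trusted_list_names)
  tmap <- lapply(tmap, normalize_condition_name)
  names(tmap) <- normalize_condition_name(df$condition)
  tmap <- structure(tmap, class = "trusted_source_map")
  if (!is.null(trusted)) validate_trusted_map(tmap, trusted)
  tmap
}

validate_trusted_map <- function(tmap, trusted) {
  referenced <- unique(unlist(tmap, use.names = FALSE))
  missing <- setdiff(referenced, names(trusted))
  if (length(missing)) {
    stop_config(paste0(
      "Trusted-source map references list(s) absent from the trusted collection: ",
      toString(missing)
    ))
  }
  invisible(tmap)
}
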