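# Ontology mapping (preprocessing stage): convert baseline codelists from
# legacy UK primary-care ontologies (Read v2, CTV3, Medcode) to SNOMED CT
# using TRUD-style cross-map tables. One source code may map to several
# SNOMED concepts; maps are expanded (recall-favouring) because draft
# codelists prioritise capture and the downstream shrinking/review stages
# prune. Unmapped codes are never silently dropped: they are itemised in the
# mapping report.

#' Column dialect of a mapping table
#'
#' TRUD releases name their columns inconsistently; the dialect names the
#' columns holding the source code, source ontology, target SNOMED id and
#' (optionally) the assurance flag.
#'
#' @param source_code,source_ontology,snomed_id,assured Column names in the
#'   file; `assured = NULL` if the file carries no assurance marker.
#' @return A named list used by [read_mapping_table()].
#' @export
mapping_dialect <- function(source_code = "source_code",
                            source_ontology = "source_ontology",
                            snomed_id = "snomed_id",
                            assured = "assured") {
  list(
    source_code = source_code, source_ontology = source_ontology,
    snomed_id = snomed_id, assured = assured
  )
}

#' Load an ontology mapping table
#'
#' Rows whose target fails SNOMED id validation are dropped and counted in a
#' warning; duplicate (source, target) rows are deduplicated.
#'
#' @param path Tab- or comma-delimited file.
#' @param dialect Column dialect, see [mapping_dialect()].
#' @return A `mapping_table` tibble with columns `source_ontology`,
#'   `source_code`, `snomed_id`, `assured`.
#' @export
read_mapping_table <- function(path, dialect = mapping_dialect()) {
  df <- read_delim_quiet(path, readr::cols(.default = readr::col_character()))
  require_columns(df, unlist(dialect[c("source_code", "source_ontology", "snomed_id")]), path)
  assured <- if (!is.null(dialect$assured) && dialect$assured %in% names(df)) {
    tolower(df[[dialect$assured]]) %in% c("1", "true", "t", "yes", "y")
  } else {
    rep(TRUE, nrow(df))
  }
  tb <- tibble::tibble(
    source_ontology = df[[dialect$source_ontology]],
    source_code = df[[dialect$source_code]],
    snomed_id = df[[dialect$snomed_id]],
    assured = assured
  )
  bad <- !validate_sctid(tb$snomed_id)
  if (any(bad)) {
    rlang::warn(paste0(
      "Dropped ", sum(bad), " mapping row(s) with invalid SNOMED target id."
    ))
    tb <- tb[!bad, , drop = FALSE]
  }
  tb <- dplyr::distinct(tb, .data$source_ontology, .data$source_code,
    .data$snomed_id,
    .keep_all = TRUE
  )
  structure(
    tb[order(tb$source_ontology, tb$source_code, tb$snomed_id), ],
    class = c("mapping_table", class(tb))
  )
}

#' Convert a codelist to SNOMED
#'
#' SNOMED entries pass through unchanged. Each legacy entry is replaced by one
#' output entry per mapping target; provenance gains a `mapped:<ontology>:<code>`
#' label recording the source code. Output is deduplicated by SNOMED id.
#' Legacy codes absent from the table are excluded from the output list but
#' fully itemised in the mapping report.
#'
#' @param x A `codelist`.
#' @param table A `mapping_table` from [read_mapping_table()].
#' @param assured_only Use only assured mapping rows (strict mode)?
#' @return A list with elements `codelist` (all-SNOMED) and `report` (a
#'   `mapping_report`: `n_input_codes`, `n_mapped_source_codes`,
#'   `n_unmapped_source_codes`, `n_passthrough`, `n_output_snomed_codes`,
#'   `unmapped` entry tibble). `n_mapped_source_codes` counts every input
#'   entry with at least one output (pass-through SNOMED entries map to
#'   themselves), so mapped + unmapped = input.
#' @export
map_to_snomed <- function(x, table, assured_only = FALSE) {
  stopifnot(inherits(x, "codelist"))
  e <- entries(x)
  if (assured_only) table <- table[table$assured, , drop = FALSE]
  is_snomed <- e$ontology == "SNOMED"
  passthrough <- e[is_snomed, , drop = FALSE]
  legacy <- e[!is_snomed, , drop = FALSE]

  mapped_rows <- list()
  unmapped_idx <- logical(nrow(legacy))
  if (nrow(legacy)) {
    for (i in seq_len(nrow(legacy))) {
      hits <- table[table$source_ontology == legacy$ontology[i] &
        table$source_code == legacy$code_id[i], , drop = FALSE]
      if (nrow(hits) == 0L) {
        unmapped_idx[i] <- TRUE
        next
      }
      mapped_rows[[length(mapped_rows) + 1L]] <- tibble::tibble(
        ontology = "SNOMED",
        code_id = hits$snomed_id,
        term = legacy$term[i],
        provenance = prov_union(
          rep(legacy$provenance[i], nrow(hits)),
          paste0("mapped:", legacy$ontology[i], ":", legacy$code_id[i])
        ),
        status = legacy$status[i],
        boundary_case = legacy$boundary_case[i]
      )
    }
  }
  out_entries <- dplyr::bind_rows(c(list(passthrough), mapped_rows))
  if (nrow(out_entries) == 0L) {
    out_entries <- code_entries(character(0), character(0))
  }
  out <- codelist(condition_name(x), out_entries)
  report <- structure(
    list(
      n_input_codes = nrow(e),
      n_mapped_source_codes = nrow(e) - sum(unmapped_idx),
      n_unmapped_source_codes = sum(unmapped_idx),
      n_passthrough = nrow(passthrough),
      n_output_snomed_codes = n_codes(out),
      unmapped = legacy[unmapped_idx, , drop = FALSE]
    ),
    class = "mapping_report"
  )
  list(codelist = out, report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf(
    "<mapping_report> %d input code(s): %d mapped (%d pass-through), %d unmapped; %d SNOMED output(s)\n",
    x$n_input_codes, x$n_mapped_source_codes, x$n_passthrough,
    x$n_unmapped_source_codes, x$n_output_snomed_codes
  ))
  invisible(x)
}

#' Convert every codelist in a collection to SNOMED
#'
#' @param collection A `codelist_collection`.
#' @inheritParams map_to_snomed
#' @return A list with `collection` (all-SNOMED) and `reports` (named list of
#'   per-condition `mapping_report`s) plus `totals`, the summed report fields.
#' @export
map_collection_to_snomed <- function(collection, table, assured_only = FALSE) {
  stopifnot(inherits(collection, "codelist_collection"))
  results <- lapply(collection$lists, map_to_snomed, table = table, assured_only = assured_only)
  lists <- lapply(results, `[[`, "codelist")
  reports <- lapply(results, `[[`, "report")
  totals <- list(
    n_input_codes = sum(vapply(reports, `[[`, integer(1), "n_input_codes")),
    n_mapped_source_codes = sum(vapply(reports, `[[`, integer(1), "n_mapped_source_codes")),
    n_unmapped_source_codes = sum(vapply(reports, `[[`, integer(1), "n_unmapped_source_codes")),
    n_output_snomed_codes = sum(vapply(reports, `[[`, integer(1), "n_output_snomed_codes"))
  )
  list(
    collection = codelist_collection(unname(lists), collection$source_label),
    reports = reports,
    totals = totals
  )
}
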