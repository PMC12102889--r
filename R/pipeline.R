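# Phase-oriented pipeline over a project directory. Each phase reads the
# previous phase's artefacts, writes its own under out_dir/<phase>/, and
# records a manifest (input checksums, configuration hash, tool version) so a
# finished codelist release can be audited and reproduced. Artefacts are
# byte-stable: rerunning an unchanged phase rewrites identical files.

PHASES <- c(
  "synth", "preprocess", "derive", "generate", "shrink", "report",
  "review-export", "review-import"
)
# Phases needing no human input; the others consume clinician-authored files
# (directives, review sheets), which makes the manual steps replayable.
AUTOMATIC_PHASES <- c("synth", "preprocess", "derive", "shrink", "report", "review-export")

#' Load a pipeline project configuration
#'
#' A YAML file with a `paths` block (`baselines`, `mapping`, `directives`,
#' `split_rules`, `trusted`, `trusted_map`, `review_sheet`, `out_dir`) and an
#' `options` block (`strict_sctid`, `whole_word`, `seed`, fixture settings
#' for the synth phase). Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to the YAML config (or a list already in that shape, with
#'   `base_dir` naming the resolution root).
#' @return A `project_config` list.
#' @export
read_project_config <- function(path) {
  if (is.list(path)) {
    cfg <- path
    base_dir <- cfg$base_dir %||% "."
  } else {
    if (!file.exists(path)) stop_config(paste0("Config file not found: ", path))
    cfg <- yaml::read_yaml(path)
    base_dir <- dirname(normalizePath(path))
  }
  cfg$paths <- cfg$paths %||% list()
  cfg$options <- cfg$options %||% list()
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x) {
      if (grepl("^(/|[A-Za-z]:)", x)) x else file.path(base_dir, x)
    }, character(1), USE.NAMES = FALSE)
  }
  for (field in c(
    "baselines", "mapping", "directives", "split_rules",
    "trusted", "trusted_map", "review_sheet", "out_dir"
  )) {
    cfg$paths[[field]] <- resolve(cfg$paths[[field]])
  }
  cfg$paths$out_dir <- cfg$paths$out_dir %||% file.path(base_dir, "out")
  cfg$options$strict_sctid <- isTRUE(cfg$options$strict_sctid)
  cfg$options$whole_word <- isTRUE(cfg$options$whole_word)
  cfg$options$seed <- as.integer(cfg$options$seed %||% 1L)
  cfg$base_dir <- base_dir
  structure(cfg, class = "project_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[c("paths", "options")]), tmp)
  unname(tools::md5sum(tmp))
}

phase_dir <- function(config, phase) file.path(config$paths$out_dir, phase)

require_artefact <- function(path, produced_by) {
  missing <- path[!file.exists(path)]
  if (length(missing)) {
    stop_dependency(paste0(
      "Missing artefact(s) ", toString(missing),
      "; run the '", produced_by, "' phase first."
    ))
  }
  invisible(path)
}

require_inputs <- function(paths, what) {
  paths <- unlist(paths)
  if (is.null(paths) || length(paths) == 0L) {
    stop_config(paste0("Config is missing required path(s): ", what))
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_config(paste0("Configured ", what, " file(s) not found: ", toString(missing)))
  }
  invisible(paths)
}

write_manifest <- function(config, phase, inputs, outputs) {
  manifest <- list(
    phase = phase,
    mode = if (phase %in% AUTOMATIC_PHASES) "automatic" else "manual-input",
    tool = "codelistr",
    version = as.character(utils::packageVersion("codelistr")),
    config_hash = config_hash(config),
    inputs = {
      paths <- sort(unlist(inputs))
      if (length(paths)) as.list(tools::md5sum(paths)) else stats::setNames(list(), character(0))
    },
    outputs = basename(sort(unlist(outputs)))
  )
  jsonlite::write_json(
    manifest, file.path(phase_dir(config, phase), "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
}

phase_log <- function(phase) {
  mode <- if (phase %in% AUTOMATIC_PHASES) "Automatic" else "Manual-input"
  message(sprintf("[%s] phase '%s'", mode, phase))
}

#' Run one pipeline phase
#'
#' Phases mirror the framework stages: `synth` (write a synthetic project),
#' `preprocess` (ontology mapping to SNOMED), `derive` (definitive condition
#' list), `generate` (keyword drafts plus group/split restructuring),
#' `shrink` (trusted-source auto-validation and workload report), `report`
#' (comparison/new-code/size summaries), `review-export` and `review-import`
#' (clinical review round-trip). Dependent phases fail with a dependency
#' error naming the phase to run first.
#'
#' @param phase One of the phase names above.
#' @param config A config path or `project_config`.
#' @return Invisibly, a named list of artefact paths written by the phase.
#' @export
run_phase <- function(phase, config) {
  phase <- match.arg(phase, PHASES)
  config <- if (inherits(config, "project_config")) config else read_project_config(config)
  phase_log(phase)
  out <- phase_dir(config, phase)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  switch(phase,
    "synth" = phase_synth(config),
    "preprocess" = phase_preprocess(config),
    "derive" = phase_derive(config),
    "generate" = phase_generate(config),
    "shrink" = phase_shrink(config),
    "report" = phase_report(config),
    "review-export" = phase_review_export(config),
    "review-import" = phase_review_import(config)
  )
}

phase_synth <- function(config) {
  opts <- config$options
  spec <- fixture_spec(
    n_conditions = as.integer(opts$n_conditions %||% 20L),
    codes_per_condition = as.integer(unlist(opts$codes_per_condition %||% c(4L, 30L))),
    legacy_fraction = opts$legacy_fraction %||% 0.2,
    seed = opts$seed
  )
  res <- write_fixture_project(config$base_dir, spec)
  files <- file.path(config$base_dir, c(
    "baseline_a.csv", "baseline_b.csv", "mapping.csv", "directives.csv",
    "trusted.csv", "trusted_map.csv", "expected_shrink.csv", "config.yaml"
  ))
  dir.create(phase_dir(config, "synth"), recursive = TRUE, showWarnings = FALSE)
  write_manifest(config, "synth", inputs = list(), outputs = files)
  invisible(stats::setNames(as.list(files), basename(files)))
}

phase_preprocess <- function(config) {
  baselines <- require_inputs(config$paths$baselines, "baselines")
  mapping <- require_inputs(config$paths$mapping, "mapping")
  table <- read_mapping_table(mapping)
  out <- phase_dir(config, "preprocess")
  outputs <- character(0)
  report_totals <- list()
  for (path in baselines) {
    coll <- read_codelist_csv(path)
    res <- map_collection_to_snomed(coll, table)
    dest <- file.path(out, paste0(coll$source_label, ".csv"))
    write_codelist_csv(res$collection, dest)
    unmapped <- dplyr::bind_rows(lapply(res$reports, `[[`, "unmapped"))
    report_totals[[coll$source_label]] <- c(
      res$totals,
      list(unmapped = unmapped$code_id %||% character(0))
    )
    outputs <- c(outputs, dest)
  }
  report_path <- file.path(out, "mapping_report.json")
  jsonlite::write_json(report_totals, report_path, auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, report_path)
  write_manifest(config, "preprocess", inputs = c(baselines, mapping), outputs = outputs)
  invisible(list(collections = outputs))
}

read_preprocessed <- function(config) {
  pre <- phase_dir(config, "preprocess")
  expected <- file.path(pre, paste0(
    sub("\\.[^.]+$", "", basename(config$paths$baselines)), ".csv"
  ))
  require_artefact(expected, "preprocess")
  lapply(expected, read_codelist_csv)
}

phase_derive <- function(config) {
  collections <- read_preprocessed(config)
  conditions <- derive_definitive_conditions(collections)
  out <- phase_dir(config, "derive")
  dest <- file.path(out, "definitive_conditions.csv")
  readr::write_csv(
    tibble::tibble(
      canonical_key = conditions$canonical_key,
      display_name = conditions$display_name,
      aliases = vapply(conditions$aliases, paste, character(1), collapse = ";"),
      sources = vapply(conditions$sources, paste, character(1), collapse = ";"),
      member_keys = vapply(conditions$member_keys, paste, character(1), collapse = ";"),
      n_codes = vapply(conditions$n_codes_per_source, sum, integer(1))
    ),
    dest,
    progress = FALSE
  )
  write_manifest(config, "derive",
    inputs = file.path(
      phase_dir(config, "preprocess"),
      paste0(sub("\\.[^.]+$", "", basename(config$paths$baselines)), ".csv")
    ),
    outputs = dest
  )
  invisible(list(definitive_conditions = dest))
}

# Keywords for a definitive condition: its aliases, minus very short ones
# (2-3 letter abbreviations over-capture as substrings; they still serve name
# unification).
condition_keywords <- function(aliases) {
  kw <- aliases[nchar(aliases) >= 4L]
  if (length(kw) == 0L) kw <- aliases
  kw
}

phase_generate <- function(config) {
  collections <- read_preprocessed(config)
  require_artefact(
    file.path(phase_dir(config, "derive"), "definitive_conditions.csv"), "derive"
  )
  directives_path <- require_inputs(config$paths$directives, "directives")
  directives <- read_directives_csv(directives_path)
  conditions <- derive_definitive_conditions(collections)
  parts <- partition_by_directive(conditions, directives)

  lists <- lapply(seq_len(nrow(parts$simple)), function(i) {
    cl <- keyword_search_codes(
      condition_keywords(parts$simple$aliases[[i]]), collections,
      condition_name = parts$simple$display_name[i],
      whole_word = config$options$whole_word
    )
    if (n_codes(cl) == 0L) {
      rlang::warn(paste0(
        "Keyword draft for '", parts$simple$display_name[i], "' is empty."
      ))
    }
    cl
  })
  drafts <- codelist_collection(lists, "drafts")

  if (nrow(parts$complex)) {
    rules <- if (!is.null(config$paths$split_rules)) {
      require_inputs(config$paths$split_rules, "split_rules")
      read_split_rules_csv(config$paths$split_rules)
    } else {
      NULL
    }
    for (i in seq_len(nrow(parts$complex))) {
      directive <- directives[parts$complex$directive_idx[i], , drop = FALSE]
      seed_cl <- keyword_search_codes(
        condition_keywords(parts$complex$aliases[[i]]), collections,
        condition_name = parts$complex$display_name[i],
        whole_word = config$options$whole_word
      )
      drafts <- collection_add(drafts, seed_cl)
      drafts <- if (directive$action == "group") {
        apply_group(directive, drafts)
      } else {
        if (is.null(rules)) {
          stop_config(paste0(
            "Split directive for '", directive$condition,
            "' but no split_rules path configured."
          ))
        }
        apply_split(directive, rules, drafts, whole_word = config$options$whole_word)
      }
    }
  }

  out <- phase_dir(config, "generate")
  dest <- file.path(out, "drafts.csv")
  write_codelist_csv(drafts, dest)
  write_manifest(config, "generate",
    inputs = c(
      directives_path,
      file.path(phase_dir(config, "derive"), "definitive_conditions.csv")
    ),
    outputs = dest
  )
  invisible(list(drafts = dest))
}

phase_shrink <- function(config) {
  drafts_path <- file.path(phase_dir(config, "generate"), "drafts.csv")
  require_artefact(drafts_path, "generate")
  trusted_path <- require_inputs(config$paths$trusted, "trusted")
  tmap_path <- require_inputs(config$paths$trusted_map, "trusted_map")
  drafts <- read_codelist_csv(drafts_path, "drafts")
  trusted <- read_codelist_csv(trusted_path, "trusted")
  tmap <- read_trusted_map_csv(tmap_path, trusted)
  res <- shrink_collection(drafts, tmap, trusted)
  out <- phase_dir(config, "shrink")
  shrunk_path <- file.path(out, "shrunk.csv")
  report_path <- file.path(out, "shrink_report.csv")
  write_codelist_csv(res$collection, shrunk_path)
  write_shrink_report_csv(res$report, report_path)
  write_manifest(config, "shrink",
    inputs = c(drafts_path, trusted_path, tmap_path),
    outputs = c(shrunk_path, report_path)
  )
  invisible(list(shrunk = shrunk_path, report = report_path, result = res))
}

phase_report <- function(config) {
  shrunk_path <- file.path(phase_dir(config, "shrink"), "shrunk.csv")
  require_artefact(shrunk_path, "shrink")
  shrunk <- read_codelist_csv(shrunk_path, "final")
  trusted <- read_codelist_csv(require_inputs(config$paths$trusted, "trusted"), "trusted")
  tmap <- read_trusted_map_csv(require_inputs(config$paths$trusted_map, "trusted_map"), trusted)
  baselines <- lapply(config$paths$baselines, read_codelist_csv)

  out <- phase_dir(config, "report")
  comparison_path <- file.path(out, "comparison.csv")
  new_codes_path <- file.path(out, "new_codes.csv")
  profile_path <- file.path(out, "size_profile.csv")
  readr::write_csv(
    comparison_table(c(baselines, list(shrunk))), comparison_path,
    progress = FALSE
  )
  # At this stage validated means auto_validated or approved; review-import
  # refines the approved set.
  readr::write_csv(
    new_codes_vs_trusted(shrunk, tmap, trusted), new_codes_path,
    progress = FALSE
  )
  readr::write_csv(size_profile(shrunk), profile_path, progress = FALSE)
  outputs <- c(comparison_path, new_codes_path, profile_path)
  write_manifest(config, "report", inputs = shrunk_path, outputs = outputs)
  invisible(list(
    comparison = comparison_path, new_codes = new_codes_path,
    size_profile = profile_path
  ))
}

phase_review_export <- function(config) {
  shrunk_path <- file.path(phase_dir(config, "shrink"), "shrunk.csv")
  require_artefact(shrunk_path, "shrink")
  shrunk <- read_codelist_csv(shrunk_path, "final")
  out <- phase_dir(config, "review-export")
  sheet_path <- file.path(out, "review_sheet.csv")
  export_review_sheet(shrunk, sheet_path)
  write_manifest(config, "review-export", inputs = shrunk_path, outputs = sheet_path)
  invisible(list(review_sheet = sheet_path))
}

phase_review_import <- function(config) {
  shrunk_path <- file.path(phase_dir(config, "shrink"), "shrunk.csv")
  require_artefact(shrunk_path, "shrink")
  sheet_path <- config$paths$review_sheet %||%
    file.path(phase_dir(config, "review-export"), "review_sheet.csv")
  require_artefact(sheet_path, "review-export")
  shrunk <- read_codelist_csv(shrunk_path, "final")
  out <- phase_dir(config, "review-import")
  audit_path <- file.path(out, "audit_log.csv")
  res <- import_review_decisions(sheet_path, shrunk, audit_path = audit_path)
  final_path <- file.path(out, "final.csv")
  write_codelist_csv(res$collection, final_path)
  write_manifest(config, "review-import",
    inputs = c(shrunk_path, sheet_path),
    outputs = c(final_path, audit_path)
  )
  invisible(list(final = final_path, audit_log = audit_path))
}
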