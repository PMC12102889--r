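# Synthetic study generator. Emulates the structure of a real codelist
# project - two baseline releases naming overlapping conditions under
# different name variants, a minority of codes in a legacy ontology with a
# TRUD-style mapping table, and a trusted source with planted per-condition
# coverage - so every pipeline stage can be exercised, and its output checked
# against planted ground truth, without any terminology download. Trusted
# coverage is planted as an exact count (floor(p * n) codes per condition),
# not Bernoulli-sampled, so expected shrink percentages are exact.

#' Pool of realistic condition names used by the generator
#'
#' Names are pairwise non-containing (no name is a substring of another after
#' text normalisation) so keyword-generated drafts are separable by
#' construction.
#'
#' @return A character vector of 30 condition names.
#' @export
condition_name_pool <- function() {
  c(
    "Asthma", "Anxiety", "Depression", "Heart Failure", "Atrial Fibrillation",
    "Chronic Kidney Disease", "Pulmonary Fibrosis", "Fatty Liver",
    "Alcohol Problems", "Abdominal Hernia", "Epilepsy", "Osteoporosis",
    "Cataract", "Macular Degeneration", "Hypertension", "Peptic Ulcer",
    "Bladder Dysfunction", "Chronic Tinnitus", "Migraine", "Bronchiectasis",
    "Cystic Fibrosis", "Sleep Apnoea", "Gout", "Psoriasis",
    "Parkinson Disease", "Dementia", "Bipolar Disorder",
    "Personality Disorder", "Coeliac Disease", "Glaucoma"
  )
}

TERM_MODIFIERS <- c(
  "", "Exacerbation of", "History of", "Chronic", "Acute", "Severe", "Mild",
  "Recurrent", "Suspected", "Worsening", "Follow-up of", "Screening for"
)
TERM_QUALIFIERS <- c("", "(finding)", "(disorder)", "(situation)")

#' Describe a synthetic codelist study
#'
#' @param n_conditions Number of conditions (at most
#'   `length(condition_name_pool())`).
#' @param codes_per_condition Inclusive `c(min, max)` range of codes per
#'   condition.
#' @param name_variant_rules Probabilities with which the second baseline's
#'   condition names are perturbed: `case` (case change), `underscore`
#'   (spaces to underscores), `plural` (trailing "s"), `abbreviation`
#'   (parenthesised initials appended).
#' @param legacy_fraction Share of the second baseline's codes emitted under
#'   the CTV3 ontology (with a consistent mapping table).
#' @param trusted_coverage Per-condition trusted coverage p in `[0, 1]`:
#'   a single number, a named vector over condition names, or `NULL` to draw
#'   the default mixture (65% fully covered, 25% partial on 0.30-0.95, 10%
#'   uncovered/newly introduced).
#' @param distractors_per_list Trusted-only codes added per trusted list
#'   (verifies that shrinking never imports codes absent from drafts).
#' @param seed Integer seed; identical specs give byte-identical fixtures.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_conditions = 20L,
                         codes_per_condition = c(4L, 30L),
                         name_variant_rules = list(
                           case = 0.5, underscore = 0.4,
                           plural = 0.3, abbreviation = 0.25
                         ),
                         legacy_fraction = 0.2,
                         trusted_coverage = NULL,
                         distractors_per_list = 2L,
                         seed = 1L) {
  if (n_conditions < 1L || n_conditions > length(condition_name_pool())) {
    stop_config(paste0(
      "n_conditions must be between 1 and ", length(condition_name_pool()), "."
    ))
  }
  if (length(codes_per_condition) != 2L || codes_per_condition[1] < 1L ||
    codes_per_condition[1] > codes_per_condition[2]) {
    stop_config("codes_per_condition must be a positive c(min, max) range.")
  }
  fracs <- c(unlist(name_variant_rules), legacy_fraction, trusted_coverage)
  if (any(fracs < 0 | fracs > 1)) {
    stop_config("All fractions must lie in [0, 1].")
  }
  structure(
    list(
      n_conditions = as.integer(n_conditions),
      codes_per_condition = as.integer(codes_per_condition),
      name_variant_rules = name_variant_rules,
      legacy_fraction = legacy_fraction,
      trusted_coverage = trusted_coverage,
      distractors_per_list = as.integer(distractors_per_list),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# Disjoint id-body ranges keep baseline and distractor ids collision-free by
# construction.
draw_snomed_ids <- function(n, distractor = FALSE) {
  offset <- if (distractor) 50000000L else 10000000L
  bodies <- sample.int(39999999L, n) + offset
  verhoeff_complete(as.character(bodies))
}

condition_terms <- function(stem, n) {
  grid <- expand.grid(
    modifier = TERM_MODIFIERS, qualifier = TERM_QUALIFIERS,
    stringsAsFactors = FALSE
  )
  terms <- trimws(paste(grid$modifier, stem, grid$qualifier))
  if (n > length(terms)) {
    terms <- c(terms, paste(stem, "variant", seq_len(n - length(terms))))
  }
  terms[seq_len(n)]
}

#' Generate a synthetic SNOMED vocabulary
#'
#' @param n Number of codes.
#' @param seed Optional seed (deterministic output for equal seeds).
#' @param stems Condition stems the terms are composed from.
#' @return A tibble `code_id`, `term`; ids are unique, digits-only, length
#'   6-18 and carry a valid Verhoeff check digit.
#' @export
generate_vocabulary <- function(n, seed = NULL, stems = condition_name_pool()) {
  stopifnot(n >= 1L)
  run <- function() {
    ids <- draw_snomed_ids(n)
    stem <- factor(rep_len(stems, n), levels = unique(stems))
    counts <- table(stem)
    grouped <- unlist(lapply(levels(stem), function(s) condition_terms(s, counts[[s]])))
    terms <- character(n)
    terms[order(stem)] <- grouped
    tibble::tibble(code_id = ids, term = terms)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

apply_name_variant <- function(name, rules) {
  out <- name
  last <- utils::tail(strsplit(out, " ")[[1]], 1)
  if (stats::runif(1) < rules$plural && !grepl("s$", tolower(last)) && nchar(last) >= 3L) {
    out <- paste0(out, "s")
  }
  words <- strsplit(name, " ")[[1]]
  if (stats::runif(1) < rules$abbreviation && length(words) > 1L) {
    out <- paste0(out, " (", paste(toupper(substr(words, 1, 1)), collapse = ""), ")")
  }
  if (stats::runif(1) < rules$underscore) {
    out <- gsub(" ", "_", out)
  }
  if (stats::runif(1) < rules$case) {
    out <- if (stats::runif(1) < 0.5) toupper(out) else tolower(out)
  }
  out
}

#' Generate the two baseline collections
#'
#' Two collections share the same underlying conditions: the first under the
#' canonical names, the second under planted name variants, with
#' `legacy_fraction` of its codes re-expressed in CTV3 together with a
#' consistent mapping table. The ground truth records which names co-refer
#' and the post-mapping SNOMED code set of every condition.
#'
#' @param spec A `fixture_spec`.
#' @return A list: `baseline_a`, `baseline_b` (collections), `mapping_table`,
#'   and `ground_truth` (`name_map` tibble; `code_sets`, named list of the
#'   per-condition post-mapping draft id sets; `pools`, the full per-condition
#'   vocabularies).
#' @export
generate_baselines <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    nms <- condition_name_pool()[seq_len(spec$n_conditions)]
    keys <- normalize_condition_name(nms)
    n_k <- sample(
      seq(spec$codes_per_condition[1], spec$codes_per_condition[2]),
      spec$n_conditions,
      replace = TRUE
    )
    ids <- draw_snomed_ids(sum(n_k))
    splits <- split(ids, rep(seq_along(n_k), n_k))

    pools <- list()
    lists_a <- list()
    lists_b_raw <- list()
    variant_names <- character(spec$n_conditions)
    legacy_counter <- 0L
    mapping_rows <- list()

    for (k in seq_along(nms)) {
      pool <- tibble::tibble(
        code_id = splits[[k]],
        term = condition_terms(nms[k], n_k[k])
      )
      pools[[keys[k]]] <- pool

      take_a <- sort(sample(n_k[k], max(1L, round(stats::runif(1, 0.7, 1) * n_k[k]))))
      take_b <- sort(sample(n_k[k], max(1L, round(stats::runif(1, 0.7, 1) * n_k[k]))))
      lists_a[[k]] <- codelist(nms[k], code_entries(
        pool$code_id[take_a], pool$term[take_a],
        provenance = "baseline_a"
      ))

      variant_names[k] <- apply_name_variant(nms[k], spec$name_variant_rules)
      b_entries <- code_entries(
        pool$code_id[take_b], pool$term[take_b],
        provenance = "baseline_b"
      )
      if (spec$legacy_fraction > 0 && nrow(b_entries) > 0L) {
        n_leg <- round(spec$legacy_fraction * nrow(b_entries))
        if (n_leg > 0L) {
          leg_idx <- sort(sample(nrow(b_entries), n_leg))
          legacy_codes <- sprintf("X%04d", legacy_counter + seq_len(n_leg))
          legacy_counter <- legacy_counter + n_leg
          mapping_rows[[length(mapping_rows) + 1L]] <- tibble::tibble(
            source_ontology = "CTV3",
            source_code = legacy_codes,
            snomed_id = b_entries$code_id[leg_idx],
            assured = TRUE
          )
          b_entries$ontology[leg_idx] <- "CTV3"
          b_entries$code_id[leg_idx] <- legacy_codes
        }
      }
      lists_b_raw[[k]] <- codelist(variant_names[k], b_entries)

      draft_ids <- sort(unique(pool$code_id[sort(unique(c(take_a, take_b)))]))
      attr(pools[[keys[k]]], "draft_ids") <- draft_ids
    }

    mapping_table <- if (length(mapping_rows)) {
      tb <- dplyr::bind_rows(mapping_rows)
      structure(
        tb[order(tb$source_ontology, tb$source_code), ],
        class = c("mapping_table", class(tb))
      )
    } else {
      structure(
        tibble::tibble(
          source_ontology = character(0), source_code = character(0),
          snomed_id = character(0), assured = logical(0)
        ),
        class = c("mapping_table", class(tibble::tibble()))
      )
    }

    code_sets <- lapply(pools, attr, "draft_ids")
    list(
      baseline_a = codelist_collection(lists_a, "baseline_a"),
      baseline_b = codelist_collection(lists_b_raw, "baseline_b"),
      mapping_table = mapping_table,
      ground_truth = list(
        name_map = tibble::tibble(
          condition = nms, variant = variant_names, canonical_key = keys
        ),
        code_sets = code_sets,
        pools = lapply(pools, function(p) {
          attr(p, "draft_ids") <- NULL
          p
        })
      )
    )
  })
}

#' Generate a trusted source with planted coverage
#'
#' For condition k with n_k draft codes and coverage p_k, the trusted list
#' contains exactly `floor(p_k * n_k)` codes sampled without replacement from
#' the draft, plus distractor codes absent from every draft. Conditions with
#' p_k = 0 get no trusted list and no map entry - they are "newly
#' introduced" and require full review. Larger trusted sets are sometimes
#' split over two lists to exercise multi-list condition maps.
#'
#' @param drafts The draft `codelist_collection` the coverage refers to.
#' @param coverage Per-condition coverage: single number, named vector over
#'   canonical keys, or `NULL` for the default mixture (see
#'   [fixture_spec()]).
#' @param seed Integer seed.
#' @param distractors_per_list Trusted-only codes per list.
#' @return A list: `trusted` (collection), `tmap` (`trusted_source_map`),
#'   `expected_report` (the `shrink_report` that shrinking must reproduce),
#'   `coverage` (the realised named coverage vector).
#' @export
generate_trusted_source <- function(drafts, coverage = NULL, seed = 1L,
                                    distractors_per_list = 2L) {
  stopifnot(inherits(drafts, "codelist_collection"))
  keys <- sort(names(drafts))
  withr::with_seed(seed, {
    if (is.null(coverage)) {
      kind <- sample(c("full", "partial", "zero"), length(keys),
        replace = TRUE, prob = c(0.65, 0.25, 0.10)
      )
      coverage <- stats::setNames(ifelse(
        kind == "full", 1,
        ifelse(kind == "zero", 0, stats::runif(length(keys), 0.30, 0.95))
      ), keys)
    } else if (is.null(names(coverage))) {
      coverage <- stats::setNames(rep_len(coverage, length(keys)), keys)
    }
    missing_cov <- setdiff(keys, names(coverage))
    if (length(missing_cov)) {
      stop_config(paste0("No coverage given for: ", toString(missing_cov)))
    }

    trusted_lists <- list()
    tmap_entries <- list()
    rows <- vector("list", length(keys))
    for (i in seq_along(keys)) {
      key <- keys[i]
      e <- entries(drafts[[key]])
      n <- nrow(e)
      p <- coverage[[key]]
      m <- floor(p * n)
      rows[[i]] <- tibble::tibble(
        canonical_key = key, n_draft = n, n_auto_validated = as.integer(m),
        n_remaining = as.integer(n - m), shrink_pct = round(100 * m / n, 2)
      )
      if (p == 0) next # newly introduced: no trusted list, no map entry

      picked <- e[sort(sample(n, m)), c("code_id", "term"), drop = FALSE]
      two_lists <- m >= 4L && stats::runif(1) < 0.3
      chunks <- if (two_lists) {
        split(seq_len(m), rep(1:2, c(ceiling(m / 2), floor(m / 2))))
      } else {
        list(seq_len(m))
      }
      list_names <- paste("ref", key, c("", "b")[seq_along(chunks)])
      list_names <- trimws(list_names)
      for (j in seq_along(chunks)) {
        chunk <- picked[chunks[[j]], , drop = FALSE]
        d_ids <- if (distractors_per_list > 0L) {
          draw_snomed_ids(distractors_per_list, distractor = TRUE)
        } else {
          character(0)
        }
        ent <- code_entries(
          c(chunk$code_id, d_ids),
          c(chunk$term, paste("Unrelated reference concept", seq_along(d_ids))),
          provenance = "trusted_ref", status = "approved"
        )
        trusted_lists[[length(trusted_lists) + 1L]] <- codelist(list_names[j], ent)
      }
      tmap_entries[[key]] <- normalize_condition_name(list_names)
    }

    rows <- dplyr::bind_rows(rows)
    trusted <- codelist_collection(trusted_lists, "trusted_ref")
    tmap <- structure(tmap_entries, class = "trusted_source_map")
    expected <- structure(
      list(
        rows = rows,
        overall_pct = round(100 * sum(rows$n_auto_validated) / sum(rows$n_draft), 2),
        macro_pct = round(mean(rows$shrink_pct), 2),
        duplicates = cross_condition_duplicates(drafts)
      ),
      class = "shrink_report"
    )
    list(
      trusted = trusted, tmap = tmap,
      expected_report = expected, coverage = coverage
    )
  })
}

# Draft collection implied by the planted ground truth: per condition, the
# union of both baselines' codes, post-mapping.
ground_truth_drafts <- function(baselines) {
  gt <- baselines$ground_truth
  lists <- lapply(seq_len(nrow(gt$name_map)), function(k) {
    key <- gt$name_map$canonical_key[k]
    pool <- gt$pools[[key]]
    sel <- pool[pool$code_id %in% gt$code_sets[[key]], , drop = FALSE]
    codelist(gt$name_map$condition[k], code_entries(
      sel$code_id, sel$term,
      provenance = "draft", status = "draft"
    ))
  })
  codelist_collection(lists, "drafts")
}

#' Write a complete synthetic project to disk
#'
#' Emits every input file of a codelist project in the package's external
#' formats - two baseline codelist CSVs, the mapping table, an all-keep
#' directive table, the trusted-source CSV and condition map, a pipeline
#' `config.yaml`, and `expected_shrink.csv` holding the planted per-condition
#' shrink percentages (the recovery oracle).
#'
#' @param dir Output directory (created if absent).
#' @param spec A `fixture_spec`.
#' @return Invisibly, a list with the generated objects (`baselines`,
#'   `trusted`, `expected_report`, `config_path`).
#' @export
write_fixture_project <- function(dir, spec = fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  baselines <- generate_baselines(spec)
  drafts <- ground_truth_drafts(baselines)
  trusted <- generate_trusted_source(
    drafts,
    coverage = spec$trusted_coverage,
    seed = spec$seed + 1L,
    distractors_per_list = spec$distractors_per_list
  )

  write_codelist_csv(baselines$baseline_a, file.path(dir, "baseline_a.csv"))
  write_codelist_csv(baselines$baseline_b, file.path(dir, "baseline_b.csv"))
  readr::write_csv(
    tibble::as_tibble(baselines$mapping_table),
    file.path(dir, "mapping.csv"),
    progress = FALSE
  )
  gt <- baselines$ground_truth
  readr::write_csv(
    tibble::tibble(
      condition = gt$name_map$condition, action = "keep",
      merged_name = "", split_targets = "", related_terms = "", comment = ""
    ),
    file.path(dir, "directives.csv"),
    progress = FALSE
  )
  write_codelist_csv(trusted$trusted, file.path(dir, "trusted.csv"))
  readr::write_csv(
    tibble::tibble(
      condition = names(trusted$tmap),
      trusted_list_names = vapply(trusted$tmap, paste, character(1), collapse = ";")
    ),
    file.path(dir, "trusted_map.csv"),
    progress = FALSE
  )
  write_shrink_report_csv(trusted$expected_report, file.path(dir, "expected_shrink.csv"))

  config <- list(
    paths = list(
      baselines = c("baseline_a.csv", "baseline_b.csv"),
      mapping = "mapping.csv",
      directives = "directives.csv",
      trusted = "trusted.csv",
      trusted_map = "trusted_map.csv",
      out_dir = "out"
    ),
    options = list(
      strict_sctid = FALSE, whole_word = FALSE, seed = spec$seed
    )
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  invisible(list(
    baselines = baselines, drafts = drafts, trusted = trusted,
    expected_report = trusted$expected_report, config_path = config_path
  ))
}
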