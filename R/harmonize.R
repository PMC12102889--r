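# Condition-name harmonisation across baselines: derive the definitive
# condition list (unifying name variants via alias overlap), partition it by
# clinician directive, and search for related condition names ahead of
# group/split work. Unification is exact normalised-string equality between
# alias sets — connected components over the alias-overlap relation — never
# fuzzy similarity, so every merge is auditable.

DIRECTIVE_ACTIONS <- c("keep", "group", "split")

#' Create a clinician directive
#'
#' One keep/group/split instruction on a condition name, as recorded during
#' the clinical-intervention pass (which works on condition names only, never
#' on individual codes).
#'
#' @param condition Condition name the directive applies to.
#' @param action `"keep"` (leave the codelist alone), `"group"` (merge with
#'   related lists under one name) or `"split"` (divide into sub-conditions).
#' @param related_terms Keyword strings used to find related condition names;
#'   defaults to the condition's own normalised name.
#' @param targets For `split`, at least two output condition names; for
#'   `group`, exactly one merged name; empty for `keep`.
#' @param comment Free-text clinician comment.
#' @return A one-row `condition_directives` tibble.
#' @export
condition_directive <- function(condition, action,
                                related_terms = character(0),
                                targets = character(0),
                                comment = "") {
  if (!action %in% DIRECTIVE_ACTIONS) {
    stop_config(paste0("Unknown directive action: '", action, "'"))
  }
  if (action == "split" && length(targets) < 2L) {
    stop_config(paste0("Split directive for '", condition, "' needs >= 2 targets."))
  }
  if (action == "group" && length(targets) != 1L) {
    stop_config(paste0("Group directive for '", condition, "' needs exactly 1 merged name."))
  }
  if (action == "keep" && length(targets) != 0L) {
    stop_config(paste0("Keep directive for '", condition, "' must have no targets."))
  }
  structure(
    tibble::tibble(
      condition = condition,
      canonical_key = normalize_condition_name(condition),
      action = action,
      related_terms = list(related_terms),
      targets = list(targets),
      comment = comment
    ),
    class = c("condition_directives", class(tibble::tibble()))
  )
}

# Flatten collections into one row per (source, condition) with alias sets.
condition_items <- function(collections) {
  rows <- lapply(collections, function(coll) {
    lapply(unname(coll$lists), function(cl) {
      tibble::tibble(
        source_label = coll$source_label,
        condition_name = condition_name(cl),
        canonical_key = canonical_key(cl),
        aliases = list(extract_aliases(condition_name(cl))),
        n_codes = n_codes(cl)
      )
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}

#' Derive the definitive condition list across baselines
#'
#' Conditions whose alias sets intersect are unified into one definitive
#' condition (connected components over the alias-overlap relation). The
#' display name of a component is its longest source name (ties broken
#' lexicographically); output is sorted by canonical key.
#'
#' @param ... One or more `codelist_collection`s (or a single list of them).
#' @return A `definitive_conditions` tibble: `canonical_key`, `display_name`,
#'   `aliases` (list), `sources` (list), `n_codes_per_source` (list of named
#'   integer vectors), `member_keys` (list: canonical keys of the unified
#'   source conditions).
#' @export
derive_definitive_conditions <- function(...) {
  collections <- list(...)
  if (length(collections) == 1L && !inherits(collections[[1]], "codelist_collection")) {
    collections <- collections[[1]]
  }
  if (length(collections) == 0L) {
    stop_invalid("At least one collection is required.")
  }
  items <- condition_items(collections)
  if (nrow(items) == 0L) {
    return(empty_definitive_conditions())
  }

  # Connected components over a bipartite item--alias graph: two items are in
  # the same component iff their alias sets (transitively) intersect.
  item_ids <- paste0("item::", seq_len(nrow(items)))
  edge_df <- dplyr::bind_rows(lapply(seq_len(nrow(items)), function(i) {
    tibble::tibble(from = item_ids[i], to = paste0("alias::", items$aliases[[i]]))
  }))
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE)
  comp <- igraph::components(g)$membership
  items$component <- comp[item_ids]

  rows <- lapply(split(seq_len(nrow(items)), items$component), function(idx) {
    it <- items[idx, , drop = FALSE]
    nm <- unique(it$condition_name)
    display <- nm[order(-nchar(nm), nm)][1]
    per_source <- vapply(
      split(it$n_codes, it$source_label), sum, integer(1)
    )
    tibble::tibble(
      canonical_key = normalize_condition_name(display),
      display_name = display,
      aliases = list(sort(unique(unlist(it$aliases)))),
      sources = list(sort(unique(it$source_label))),
      n_codes_per_source = list(per_source),
      member_keys = list(sort(unique(it$canonical_key)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$canonical_key), , drop = FALSE]
  structure(out, class = c("definitive_conditions", class(tibble::tibble())))
}

empty_definitive_conditions <- function() {
  structure(
    tibble::tibble(
      canonical_key = character(0), display_name = character(0),
      aliases = list(), sources = list(), n_codes_per_source = list(),
      member_keys = list()
    ),
    class = c("definitive_conditions", class(tibble::tibble()))
  )
}

match_directive <- function(conditions, directives) {
  # index of the directive matching each condition (via canonical_key against
  # the condition's alias set), NA when none
  vapply(seq_len(nrow(conditions)), function(i) {
    hits <- which(directives$canonical_key %in% conditions$aliases[[i]])
    if (length(hits) == 0L) return(NA_integer_)
    if (length(hits) > 1L) {
      stop_config(paste0(
        "Condition '", conditions$display_name[i],
        "' matches multiple directives: ",
        toString(directives$condition[hits])
      ))
    }
    hits
  }, integer(1))
}

#' Partition definitive conditions by directive type
#'
#' `keep` directives mark simple conditions (processed fully automatically);
#' `group`/`split` mark complex conditions needing directive-driven
#' restructuring. Every condition must have exactly one matching directive.
#'
#' @param conditions A `definitive_conditions` tibble.
#' @param directives A `condition_directives` tibble.
#' @return A list with `simple` and `complex`: subsets of `conditions` (each
#'   with an `action` and `directive_idx` column added), both sorted by
#'   canonical key.
#' @export
partition_by_directive <- function(conditions, directives) {
  idx <- match_directive(conditions, directives)
  missing_dir <- conditions$canonical_key[is.na(idx)]
  unmatched <- setdiff(directives$canonical_key, directives$canonical_key[idx[!is.na(idx)]])
  if (length(missing_dir) || length(unmatched)) {
    parts <- c(
      if (length(missing_dir)) {
        paste0("condition(s) without a directive: ", toString(missing_dir))
      },
      if (length(unmatched)) {
        paste0("directive(s) without a condition: ", toString(unmatched))
      }
    )
    stop_config(paste0("Unmatched directives - ", paste(parts, collapse = "; ")))
  }
  conditions$action <- directives$action[idx]
  conditions$directive_idx <- idx
  simple <- conditions[conditions$action == "keep", , drop = FALSE]
  complex <- conditions[conditions$action != "keep", , drop = FALSE]
  list(
    simple = simple[order(simple$canonical_key), , drop = FALSE],
    complex = complex[order(complex$canonical_key), , drop = FALSE]
  )
}

#' Find condition names related to a directive
#'
#' Returns every definitive condition one of whose aliases contains any of
#' the directive's related terms as a case-insensitive substring (the worked
#' grouping examples speak of names which "consist of" the target phrase).
#' The directive's own condition is always included when present.
#'
#' @param target A one-row `condition_directives` tibble (or a row index into
#'   one).
#' @param conditions A `definitive_conditions` tibble.
#' @return Sorted character vector of matching canonical keys (possibly
#'   empty).
#' @export
find_related_conditions <- function(target, conditions) {
  stopifnot(nrow(target) == 1L)
  terms <- target$related_terms[[1]]
  if (length(terms) == 0L || all(!nzchar(trimws(terms)))) {
    terms <- target$condition
  }
  term_keys <- normalize_condition_name(terms)
  hit <- vapply(seq_len(nrow(conditions)), function(i) {
    aliases <- conditions$aliases[[i]]
    any(vapply(
      term_keys,
      function(tk) any(grepl(tk, aliases, fixed = TRUE)),
      logical(1)
    ))
  }, logical(1))
  own <- vapply(
    conditions$aliases,
    function(a) target$canonical_key %in% a, logical(1)
  )
  sort(conditions$canonical_key[hit | own])
}
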