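# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own set machinery: plain data frames, loops and base
# set operations only.

# Quick codelist builder: ids/terms generated from a stem.
mk_codelist <- function(name, ids, terms = NULL, provenance = "src",
                        status = "draft", ontology = "SNOMED") {
  if (is.null(terms)) terms <- paste(name, "concept", seq_along(ids))
  codelist(name, code_entries(ids, terms,
    ontology = ontology,
    provenance = provenance, status = status
  ))
}

# Valid random SNOMED ids outside the generator's ranges.
rand_ids <- function(n, lo = 100000L, hi = 999999L) {
  verhoeff_complete(as.character(sample(lo:hi, n)))
}

# Brute-force union of entry tables by (ontology, code_id): provenance label
# sets unioned, no status logic (callers check status separately).
oracle_union <- function(...) {
  frames <- lapply(list(...), function(cl) {
    e <- entries(cl)
    data.frame(
      ontology = e$ontology, code_id = e$code_id,
      provenance = e$provenance, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, frames)
  keys <- unique(paste(df$ontology, df$code_id))
  out <- lapply(keys, function(k) {
    rows <- df[paste(df$ontology, df$code_id) == k, ]
    labels <- unique(unlist(strsplit(rows$provenance, ";", fixed = TRUE)))
    list(key = k, provenance = sort(labels[nzchar(labels)]))
  })
  names(out) <- keys
  out
}

# Brute-force connected components by repeated transitive closure over
# pairwise alias-set intersection. items: list of character alias sets.
oracle_components <- function(alias_sets) {
  n <- length(alias_sets)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
          length(intersect(alias_sets[[i]], alias_sets[[j]])) > 0) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# A tiny ready-made asthma/liver universe used across files.
demo_collection <- function(label = "demo") {
  codelist_collection(list(
    mk_codelist("Asthma", c("195967001", "281239006"),
      c("Asthma", "Exacerbation of asthma"),
      provenance = label
    ),
    mk_codelist("Liver Conditions", c("831000119103", "197321007", "197315008"),
      c("Alcoholic liver disease", "Fatty liver", "Cirrhosis of liver"),
      provenance = label
    )
  ), label)
}
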