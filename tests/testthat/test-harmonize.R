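coll_of <- function(label, ...) {
  nms <- c(...)
  codelist_collection(
    lapply(seq_along(nms), function(i) {
      mk_codelist(nms[i], rand_ids(2, 10000L + 100L * i, 10000L + 100L * i + 99L),
        provenance = label
      )
    }),
    label
  )
}

test_that("abbreviation aliases unify name variants across baselines", {
  withr::with_seed(3, {
    a <- coll_of("efi", "COPD", "Asthma")
    b <- coll_of("serendip", "Chronic Obstructive Pulmonary Disease (COPD)", "Anxiety")
    out <- derive_definitive_conditions(a, b)
    expect_equal(nrow(out), 3L)
    copd <- out[out$canonical_key == "chronic obstructive pulmonary disease", ]
    expect_equal(nrow(copd), 1L)
    expect_setequal(copd$sources[[1]], c("efi", "serendip"))
    expect_identical(copd$display_name, "Chronic Obstructive Pulmonary Disease (COPD)")
    # no alias overlap -> separate conditions
    expect_true(all(c("asthma", "anxiety") %in% out$canonical_key))
  })
})

test_that("pairwise alias links close transitively, matching the brute-force oracle", {
  withr::with_seed(5, {
    # A ~ B via "hf", B ~ C via "heart failure": one component of three names
    a <- coll_of("s1", "Heart Failure (HF)", "Gout")
    b <- coll_of("s2", "HF", "Cardiac Failure (HF)")
    c3 <- coll_of("s3", "Heart failure")
    out <- derive_definitive_conditions(a, b, c3)
    alias_sets <- list(
      extract_aliases("Heart Failure (HF)"), extract_aliases("Gout"),
      extract_aliases("HF"), extract_aliases("Cardiac Failure (HF)"),
      extract_aliases("Heart failure")
    )
    expect_equal(nrow(out), length(unique(oracle_components(alias_sets))))
    hf <- out[vapply(out$aliases, function(al) "hf" %in% al, logical(1)), ]
    expect_equal(nrow(hf), 1L)
    expect_setequal(hf$sources[[1]], c("s1", "s2", "s3"))
  })
})

test_that("unification is order-independent and bounded by input name count", {
  withr::with_seed(9, {
    a <- coll_of("x", "Asthma", "COPD", "Migraine")
    b <- coll_of("y", "asthma", "Chronic Obstructive Pulmonary Disease (COPD)")
    fwd <- derive_definitive_conditions(a, b)
    rev <- derive_definitive_conditions(b, a)
    expect_identical(fwd$canonical_key, rev$canonical_key)
    expect_identical(fwd$aliases, rev$aliases)
    expect_lte(nrow(fwd), length(a$lists) + length(b$lists))
    # disjoint names: count equality
    d1 <- coll_of("x", "Asthma", "Gout")
    d2 <- coll_of("y", "Anxiety")
    expect_equal(nrow(derive_definitive_conditions(d1, d2)), 3L)
  })
})

test_that("directives partition conditions into simple and complex", {
  withr::with_seed(21, {
    coll <- coll_of("base", "Asthma", "Gout", "Anxiety", "Cataract", "Migraine")
    conds <- derive_definitive_conditions(list(coll))
    directives <- dplyr::bind_rows(
      condition_directive("Asthma", "keep"),
      condition_directive("Gout", "keep"),
      condition_directive("Anxiety", "keep"),
      condition_directive("Cataract", "split", targets = c("Cataract Left", "Cataract Right")),
      condition_directive("Migraine", "group", targets = "Headache Disorders")
    )
    parts <- partition_by_directive(conds, directives)
    expect_equal(nrow(parts$simple), 3L)
    expect_equal(nrow(parts$complex), 2L)
    # a true partition
    expect_setequal(
      c(parts$simple$canonical_key, parts$complex$canonical_key),
      conds$canonical_key
    )
    expect_length(intersect(parts$simple$canonical_key, parts$complex$canonical_key), 0L)

    all_keep <- dplyr::bind_rows(lapply(
      c("Asthma", "Gout", "Anxiety", "Cataract", "Migraine"),
      condition_directive,
      action = "keep"
    ))
    parts2 <- partition_by_directive(conds, all_keep)
    expect_equal(nrow(parts2$simple), 5L)
    expect_equal(nrow(parts2$complex), 0L)

    with_foo <- dplyr::bind_rows(all_keep, condition_directive("Foo", "keep"))
    err <- expect_error(
      partition_by_directive(conds, with_foo),
      class = "codelistr_config_error"
    )
    expect_match(conditionMessage(err), "foo")
    expect_error(
      partition_by_directive(conds, all_keep[-1, ]),
      class = "codelistr_config_error"
    )
  })
})

test_that("directive shape constraints are enforced", {
  expect_error(condition_directive("X", "split", targets = "only one"),
    class = "codelistr_config_error"
  )
  expect_error(condition_directive("X", "group", targets = c("a", "b")),
    class = "codelistr_config_error"
  )
  expect_error(condition_directive("X", "keep", targets = "a"),
    class = "codelistr_config_error"
  )
  expect_error(condition_directive("X", "merge"), class = "codelistr_config_error")
})

test_that("related-condition search is substring-based over aliases", {
  withr::with_seed(33, {
    coll <- coll_of(
      "base", "Macular Degeneration", "Visual Impairment and Blindness",
      "Cataract", "Visual impairment"
    )
    conds <- derive_definitive_conditions(list(coll))
    d_vi <- condition_directive("Visual impairment", "split",
      related_terms = "visual impairment",
      targets = c("Visual Impairment Diabetic", "Visual Impairment Macular")
    )
    expect_identical(
      find_related_conditions(d_vi, conds),
      c("visual impairment", "visual impairment and blindness")
    )
    # broader terms reach all four lists
    d_all <- condition_directive("Visual impairment", "split",
      related_terms = c("macular", "cataract", "visual impairment"),
      targets = c("Cataract", "Macular Degeneration")
    )
    expect_length(find_related_conditions(d_all, conds), 4L)

    # exact-name search returns the name itself; default terms are the name
    coll2 <- coll_of("base", "Alcohol Problems Others", "Alcoholic Liver Disease")
    conds2 <- derive_definitive_conditions(list(coll2))
    d_grp <- condition_directive("Alcohol Problems Others", "group", targets = "Alcohol Problems Others")
    expect_identical(find_related_conditions(d_grp, conds2), "alcohol problem other")

    d_none <- condition_directive("Gout", "group",
      related_terms = "zzz", targets = "Gout"
    )
    expect_identical(find_related_conditions(d_none, conds), character(0))
  })
})
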