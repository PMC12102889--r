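test_that("shrink percentages follow the exact-count arithmetic", {
  d <- mk_codelist("Asthma", c("195967001", "281239006", "233678006"))
  partial <- shrink_codelist(d, c("195967001", "281239006"))
  expect_equal(partial$row$shrink_pct, 66.67)
  expect_equal(partial$row$n_remaining, 1L)

  # trusted superset: fully shrunk, nothing left to review
  full <- shrink_codelist(d, c("195967001", "281239006", "233678006", "999999999"))
  expect_equal(full$row$shrink_pct, 100)
  expect_equal(full$row$n_remaining, 0L)

  disjoint <- shrink_codelist(d, c("111111111", "222222222"))
  expect_equal(disjoint$row$shrink_pct, 0)
  expect_equal(disjoint$row$n_auto_validated, 0L)

  empty <- codelist("Empty")
  expect_error(shrink_codelist(empty, "195967001"), class = "codelistr_invalid_error")
  legacy <- mk_codelist("Asthma", "X40J5", ontology = "CTV3")
  expect_error(shrink_codelist(legacy, character(0)), class = "codelistr_invalid_error")
})

test_that("shrinking changes statuses only and is idempotent", {
  d <- mk_codelist("Asthma", c("195967001", "281239006", "233678006"))
  res <- shrink_codelist(d, "195967001")
  e <- entries(res$codelist)
  expect_equal(nrow(e), n_codes(d))
  expect_identical(sort(e$code_id), sort(entries(d)$code_id))
  expect_identical(e$status[e$code_id == "195967001"], "auto_validated")
  expect_true(all(e$status[e$code_id != "195967001"] == "needs_review"))

  again <- shrink_codelist(res$codelist, "195967001")
  expect_identical(entries(again$codelist), entries(res$codelist))
  expect_identical(again$row, res$row)

  # prior review outcomes survive re-shrinking
  e2 <- entries(d)
  e2$status <- c("approved", "excluded", "draft")
  reviewed <- codelist("Asthma", e2)
  re <- shrink_codelist(reviewed, "195967001")
  statuses <- entries(re$codelist)
  expect_identical(statuses$status[statuses$code_id == entries(d)$code_id[1]], e2$status[1])
})

test_that("trusted code sets resolve as the union of mapped lists", {
  withr::with_seed(41, {
    l1 <- rand_ids(5, 100000L, 199999L)
    shared <- l1[1:2]
    l2 <- c(rand_ids(5, 200000L, 299999L), shared)
    trusted <- codelist_collection(list(
      mk_codelist("kuan neuro bladder", l1),
      mk_codelist("kuan pri bladder", l2),
      mk_codelist("kuan ocd", rand_ids(3, 300000L, 399999L))
    ), "caliber")
    tmap <- trusted_source_map(
      "Bladder Dysfunction" = c("kuan neuro bladder", "kuan pri bladder"),
      "OCD" = "kuan ocd",
      trusted = trusted
    )
    got <- resolve_trusted_codes("bladder dysfunction", tmap, trusted)
    expect_length(got, 10L) # 5 + 7 with 2 shared
    expect_setequal(got, union(l1, l2))
    expect_length(resolve_trusted_codes("ocd", tmap, trusted), 3L)
    # unmapped condition: newly introduced, full review
    expect_identical(resolve_trusted_codes("chronic tinnitus", tmap, trusted), character(0))
    # mapped-but-missing list
    bad <- trusted_source_map("OCD" = "kuan missing")
    expect_error(resolve_trusted_codes("ocd", bad, trusted),
      class = "codelistr_config_error"
    )
    expect_error(trusted_source_map("OCD" = "kuan missing", trusted = trusted),
      class = "codelistr_config_error"
    )
  })
})

test_that("collection shrinking reports code-weighted overall percentages", {
  withr::with_seed(43, {
    ids1 <- rand_ids(4, 100000L, 199999L)
    ids2 <- rand_ids(6, 200000L, 299999L)
    drafts <- codelist_collection(list(
      mk_codelist("Anxiety", ids1),
      mk_codelist("Gout", ids2)
    ), "drafts")
    trusted <- codelist_collection(
      list(mk_codelist("ref anxiety", ids1[1:3])),
      "ref"
    )
    tmap <- trusted_source_map("Anxiety" = "ref anxiety")
    res <- shrink_collection(drafts, tmap, trusted)
    rows <- res$report$rows
    expect_identical(rows$canonical_key, c("anxiety", "gout"))
    expect_equal(rows$shrink_pct, c(75, 0))
    # 3 of 10 codes auto-validated: weighted 30.00, not mean(75, 0)
    expect_equal(res$report$overall_pct, 30)
    expect_equal(res$report$macro_pct, 37.5)
    # weighted mean lies between row extremes
    expect_gte(res$report$overall_pct, min(rows$shrink_pct))
    expect_lte(res$report$overall_pct, max(rows$shrink_pct))

    all_trusted <- codelist_collection(list(
      mk_codelist("ref anxiety", ids1),
      mk_codelist("ref gout", ids2)
    ), "ref")
    res2 <- shrink_collection(
      drafts,
      trusted_source_map("Anxiety" = "ref anxiety", "Gout" = "ref gout"),
      all_trusted
    )
    expect_equal(res2$report$overall_pct, 100)
  })
})

test_that("enlarging the trusted set never decreases a shrink percentage", {
  withr::with_seed(47, {
    for (rep in 1:10) {
      ids <- rand_ids(sample(4:20, 1))
      d <- mk_codelist("C", ids)
      small <- sample(ids, sample(0:length(ids), 1))
      extra <- rand_ids(3, 5000000L, 5999999L)
      grown <- c(small, sample(ids, sample(0:length(ids), 1)), extra)
      expect_gte(
        shrink_codelist(d, grown)$row$shrink_pct,
        shrink_codelist(d, small)$row$shrink_pct
      )
    }
  })
})

test_that("cross-condition duplicates are flagged but kept in both conditions", {
  shared <- "195967001"
  drafts <- codelist_collection(list(
    mk_codelist("Asthma", c(shared, "281239006")),
    mk_codelist("Wheeze", c(shared, "301273001"))
  ), "drafts")
  trusted <- codelist_collection(list(mk_codelist("ref asthma", shared)), "ref")
  res <- shrink_collection(
    drafts, trusted_source_map("Asthma" = "ref asthma"), trusted
  )
  dup <- res$report$duplicates
  expect_identical(dup$code_id, shared)
  expect_setequal(dup$conditions[[1]], c("asthma", "wheeze"))
  expect_true(shared %in% entries(res$collection[["asthma"]])$code_id)
  expect_true(shared %in% entries(res$collection[["wheeze"]])$code_id)
})
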