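test_that("keyword search fetches every code whose term contains a keyword", {
  coll <- demo_collection("pre")
  asthma <- keyword_search_codes("asthma", coll, condition_name = "Asthma")
  expect_setequal(entries(asthma)$code_id, c("195967001", "281239006"))
  # provenance records the originating list
  expect_true(all(grepl("pre:asthma", entries(asthma)$provenance)))

  liver <- keyword_search_codes("liver", coll, condition_name = "Liver")
  expect_setequal(
    entries(liver)$term,
    c("Alcoholic liver disease", "Fatty liver", "Cirrhosis of liver")
  )
  expect_equal(n_codes(keyword_search_codes("qqq", coll)), 0L)
  expect_error(keyword_search_codes(c("liver", ""), coll),
    class = "codelistr_invalid_error"
  )
  expect_error(keyword_search_codes(character(0), coll),
    class = "codelistr_invalid_error"
  )
})

test_that("keyword search is monotone and respects whole-word mode", {
  coll <- demo_collection("pre")
  one <- keyword_search_codes("asthma", coll)
  both <- keyword_search_codes(c("asthma", "liver"), coll)
  expect_true(all(entries(one)$code_id %in% entries(both)$code_id))

  # substring mode captures "alcoholic" from "alcohol"; whole-word must not
  sub <- keyword_search_codes("alcohol", coll)
  expect_equal(n_codes(sub), 1L)
  ww <- keyword_search_codes("alcohol", coll, whole_word = TRUE)
  expect_equal(n_codes(ww), 0L)
})

test_that("grouping merges related lists under the directive name", {
  withr::with_seed(17, {
    shared <- rand_ids(1, 500000L, 599999L)
    a <- mk_codelist("Alcohol Problems", c(rand_ids(3, 600000L, 699999L), shared))
    b <- mk_codelist("Alcohol Problems Others", c(rand_ids(5, 700000L, 799999L), shared))
    gout <- mk_codelist("Gout", rand_ids(2, 800000L, 899999L))
    coll <- codelist_collection(list(a, b, gout), "drafts")

    d <- condition_directive("Alcohol Problems", "group",
      related_terms = "alcohol problem", targets = "Alcohol Problems Others"
    )
    out <- apply_group(d, coll)
    expect_setequal(names(out), c("alcohol problem other", "gout"))
    merged <- out[["alcohol problem other"]]
    # sizes 4 and 6 sharing one code -> 9
    expect_equal(n_codes(merged), 9L)
    oracle <- oracle_union(a, b)
    expect_equal(n_codes(merged), length(oracle))

    # grouping a single list is a rename: entry set unchanged
    solo <- condition_directive("Gout", "group",
      related_terms = "gout", targets = "Crystal Arthropathy"
    )
    out2 <- apply_group(solo, coll)
    expect_identical(
      entries(out2[["crystal arthropathy"]])[c("ontology", "code_id")],
      entries(gout)[c("ontology", "code_id")]
    )

    none <- condition_directive("Dementia", "group",
      related_terms = "dementia", targets = "Dementia"
    )
    expect_warning(out3 <- apply_group(none, coll), "matched no codelists")
    expect_identical(names(out3), names(coll))
  })
})

mk_split_rules <- function(condition, targets, keywords, priority = seq_along(targets)) {
  tibble::tibble(
    condition = condition, target = targets,
    keywords = keywords, priority = as.integer(priority)
  )
}

test_that("splitting partitions the source list with a materialised fallback", {
  cl <- codelist("Visual Impairment", code_entries(
    c("193570009", "267718000", "116668003", "397540003"),
    c(
      "Cataract", "Age-related macular degeneration",
      "Cataract with macular change", "Visual impairment"
    )
  ))
  coll <- codelist_collection(list(cl), "drafts")
  d <- condition_directive("Visual Impairment", "split",
    targets = c("Cataract", "Macular Degeneration")
  )
  rules <- mk_split_rules(
    "Visual Impairment", c("Cataract", "Macular Degeneration"),
    list("cataract", "macular")
  )
  out <- apply_split(d, rules, coll)
  expect_setequal(
    names(out),
    c("cataract", "macular degeneration", "visual impairment other")
  )
  # priority 1 wins where both keywords match
  expect_setequal(entries(out[["cataract"]])$code_id, c("193570009", "116668003"))
  expect_identical(entries(out[["macular degeneration"]])$code_id, "267718000")
  expect_identical(entries(out[["visual impairment other"]])$code_id, "397540003")

  # every term matching rule 1 -> all codes in target 1, fallback still
  # materialised but empty
  rules_all <- mk_split_rules(
    "Visual Impairment", c("Cataract", "Macular Degeneration"),
    list("a", "zzz")
  )
  out_all <- apply_split(d, rules_all, coll)
  expect_equal(n_codes(out_all[["cataract"]]), 4L)
  expect_equal(n_codes(out_all[["visual impairment other"]]), 0L)
  expect_true("visual impairment other" %in% names(out_all))

  expect_error(
    apply_split(d, mk_split_rules(
      "Visual Impairment", c("Cataract", "Macular Degeneration"),
      list("c", "m"), c(1L, 1L)
    ), coll),
    class = "codelistr_config_error"
  )
  expect_error(
    apply_split(d, mk_split_rules("Visual Impairment", "Cataract", list("c")), coll),
    class = "codelistr_config_error"
  )
})

test_that("random splits are exact partitions of the source entry set", {
  withr::with_seed(29, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      terms <- paste(
        sample(c("alpha", "beta", "gamma", "delta"), n, replace = TRUE),
        "finding", seq_len(n)
      )
      src <- codelist("Bucket", code_entries(rand_ids(n), terms))
      coll <- codelist_collection(list(src), "drafts")
      d <- condition_directive("Bucket", "split", targets = c("Bucket A", "Bucket B"))
      rules <- mk_split_rules("Bucket", c("Bucket A", "Bucket B"), list("alpha", "beta"))
      out <- apply_split(d, rules, coll)
      pieces <- lapply(out$lists, function(x) entries(x)$code_id)
      expect_identical(
        sort(unname(unlist(pieces))),
        sort(entries(src)$code_id)
      )
      expect_equal(sum(lengths(pieces)), n_codes(src))
      expect_false(any(duplicated(unlist(pieces))))
    }
  })
})
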