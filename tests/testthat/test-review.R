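test_that("review triggers implement the four-criteria policy", {
  # previously published list used unmodified: no review, source logged
  none <- classify_review_need(published_source = "caliber/kuan asthma")
  expect_false(none$needs_review)
  expect_identical(none$scope, "none")
  expect_identical(none$logged_source, "caliber/kuan asthma")

  novel <- classify_review_need(no_published_codelist = TRUE)
  expect_true(novel$needs_review)
  expect_identical(novel$triggered, "no_published_codelist")

  # test codes as the only trigger: only the test codes need review
  tests_only <- classify_review_need(involves_test_codes = TRUE)
  expect_identical(tests_only$scope, "test_codes")
  mixed <- classify_review_need(
    subset_of_verified_unreviewed = TRUE, involves_test_codes = TRUE
  )
  expect_identical(mixed$scope, "all")
  expect_length(mixed$triggered, 2L)

  # monotone: adding a flag never flips TRUE -> FALSE
  flags <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE), c = c(FALSE, TRUE), d = c(FALSE, TRUE))
  for (i in seq_len(nrow(flags))) {
    base <- classify_review_need(flags$a[i], flags$b[i], flags$c[i], flags$d[i])
    more <- classify_review_need(TRUE, flags$b[i], flags$c[i], flags$d[i])
    expect_true(!base$needs_review || more$needs_review)
  }
})

test_that("boundary adjudication needs two concordant votes or a casting vote", {
  expect_identical(adjudicate_boundary(c("include", "include")), "include")
  expect_identical(adjudicate_boundary(c("exclude", "exclude")), "exclude")
  # 1-1 split stays pending until a third vote
  expect_identical(adjudicate_boundary(c("include", "exclude")), "pending")
  expect_identical(adjudicate_boundary(c("include", "exclude", "exclude")), "exclude")
  expect_identical(adjudicate_boundary(c("include", "exclude", "include")), "include")
  expect_identical(adjudicate_boundary("include"), "pending")
  expect_error(adjudicate_boundary(character(0)), class = "codelistr_invalid_error")
  expect_error(adjudicate_boundary(c("include", "maybe")), class = "codelistr_invalid_error")
  expect_error(
    adjudicate_boundary(c("include", "exclude"), reviewers = c("r1", "r1")),
    class = "codelistr_reconciliation_error"
  )
})

shrunk_fixture <- function() {
  asthma <- codelist("Asthma", code_entries(
    c("195967001", "281239006", "233678006", "304527002"),
    c("Asthma", "Exacerbation of asthma", "Childhood asthma", "Acute asthma"),
    status = c("auto_validated", "needs_review", "needs_review", "needs_review"),
    boundary_case = c(0L, 0L, 1L, 0L)
  ))
  gout <- codelist("Gout", code_entries(
    "190828002", "Gout",
    status = "auto_validated"
  ))
  codelist_collection(list(asthma, gout), "final")
}

test_that("review sheets export exactly the codes still needing review", {
  coll <- shrunk_fixture()
  sheet <- export_review_sheet(coll)
  expect_equal(nrow(sheet), 3L) # fully shrunk Gout contributes no rows
  expect_true(all(sheet$condition == "Asthma"))
  expect_identical(
    sheet$Boundary_case,
    entries(coll[["asthma"]])$boundary_case[entries(coll[["asthma"]])$status == "needs_review"]
  )
  # per-condition row counts equal the shrink report's n_remaining
  expect_equal(
    nrow(sheet),
    sum(entries(coll[["asthma"]])$status == "needs_review")
  )
})

test_that("review sheets round-trip byte-stably and untouched imports are no-ops", {
  dir <- withr::local_tempdir()
  coll <- shrunk_fixture()
  p1 <- file.path(dir, "sheet1.csv")
  p2 <- file.path(dir, "sheet2.csv")
  export_review_sheet(coll, p1)
  res <- import_review_decisions(p1, coll)
  expect_identical(
    lapply(res$collection$lists, entries),
    lapply(coll$lists, entries)
  )
  expect_equal(nrow(res$audit), 0L)
  export_review_sheet(res$collection, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("imported decisions update statuses and append to the audit log", {
  dir <- withr::local_tempdir()
  audit_path <- file.path(dir, "audit.csv")
  coll <- shrunk_fixture()
  # rows sort by code id: 233678006 (boundary), 281239006, 304527002
  sheet <- export_review_sheet(coll)
  expect_identical(sheet$code, c("233678006", "281239006", "304527002"))
  sheet$reviewer_1 <- c("include", "include", "include")
  sheet$reviewer_2 <- c("exclude", "include", "include")
  sheet$reviewer_3 <- c("exclude", "", "")
  sheet$note <- c("biomarker only", "clear diagnosis", "")

  res <- import_review_decisions(sheet, coll, audit_path = audit_path)
  e <- entries(res$collection[["asthma"]])
  expect_identical(e$status[e$code_id == "281239006"], "approved")
  expect_identical(e$status[e$code_id == "233678006"], "excluded")
  expect_identical(e$status[e$code_id == "304527002"], "approved")
  # excluded boundary code is retained in the record, not deleted
  expect_true("233678006" %in% e$code_id)
  expect_equal(nrow(res$audit), 3L)
  expect_true(file.exists(audit_path))
  expect_equal(nrow(readr::read_csv(audit_path, show_col_types = FALSE)), 3L)

  # append-only: a later import adds records without rewriting prior ones
  before <- readLines(audit_path)
  sheet2 <- export_review_sheet(res$collection)
  expect_equal(nrow(sheet2), 0L)
  res2 <- import_review_decisions(sheet, res$collection, audit_path = audit_path)
  expect_identical(readLines(audit_path)[seq_along(before)], before)

  # after import nothing stays needs_review unless its decision was pending
  expect_false(any(entries(res$collection[["asthma"]])$status == "needs_review"))
})

test_that("pending splits, conflicts and unknown references are handled strictly", {
  coll <- shrunk_fixture()
  sheet <- export_review_sheet(coll)

  # 1-1 split on a boundary code stays pending (row 1 = 233678006, boundary)
  s <- sheet[1, , drop = FALSE]
  s$reviewer_1 <- "include"
  s$reviewer_2 <- "exclude"
  res <- import_review_decisions(s, coll)
  e <- entries(res$collection[["asthma"]])
  expect_identical(e$status[e$code_id == "233678006"], "needs_review")

  # a boundary outcome without two recorded votes is a reconciliation error
  s2 <- sheet[1, , drop = FALSE]
  s2$outcome <- "exclude"
  expect_error(import_review_decisions(s2, coll),
    class = "codelistr_reconciliation_error"
  )

  # outcome contradicting the votes
  s3 <- sheet[2, , drop = FALSE]
  s3$reviewer_1 <- "include"
  s3$reviewer_2 <- "include"
  s3$outcome <- "exclude"
  expect_error(import_review_decisions(s3, coll),
    class = "codelistr_reconciliation_error"
  )

  # conflicting duplicate rows for one code
  s4 <- sheet[c(1, 1), ]
  s4$reviewer_1 <- c("include", "include")
  s4$reviewer_2 <- c("include", "include")
  s4$outcome <- c("include", "exclude")
  expect_error(import_review_decisions(s4, coll),
    class = "codelistr_reconciliation_error"
  )

  # unknown (condition, code) reference
  s5 <- sheet[1, , drop = FALSE]
  s5$code <- "999999999"
  err <- expect_error(import_review_decisions(s5, coll),
    class = "codelistr_reconciliation_error"
  )
  expect_match(conditionMessage(err), "999999999")
})
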