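toy_test <- function(id = "AlwaysTrue", result = TRUE, level = "session",
                     fun = NULL) {
  qc_test(id, paste(id, "docstring."), level,
          fun %||% function(target, ctx) qc_result(result),
          passing = "p", failing = "f")
}

three_scan_session <- function(missing_in = character()) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  scans <- lapply(c("0001", "0002", "0003"), function(id) {
    list(metadata = base_pet_metadata(), nifti = !id %in% missing_in)
  })
  names(scans) <- c("0001", "0002", "0003")
  load_session(write_raw_session(root, "ALFA00001", "S1", "MR", scans))
}

test_that("scan-level tests run on every scan and conjoin outcomes", {
  nifti_test <- qc_test("HasNifti", "Each scan carries a NIfTI.", "scan",
                        function(scan, ctx) scan_has_nifti(scan),
                        passing = "p", failing = "f")
  all_ok <- run_test(nifti_test, three_scan_session())
  expect_true(all_ok$has_passed)
  expect_length(all_ok$data, 3)
  expect_true(all(vapply(all_ok$data, `[[`, logical(1), "has_passed")))

  one_bad <- run_test(nifti_test, three_scan_session(missing_in = "0002"))
  expect_false(one_bad$has_passed)
  per_scan <- vapply(one_bad$data, `[[`, logical(1), "has_passed")
  expect_equal(sum(per_scan), 2)
})

test_that("an exception inside a test yields a failed result, not an abort", {
  boom <- toy_test("Boom", fun = function(target, ctx) stop("kaput"))
  res <- run_test(boom, three_scan_session())
  expect_false(res$has_passed)
  expect_match(unlist(res$data), "kaput")
})

test_that("validators run all tests in order despite failures", {
  v <- qc_validator("V", list(
    toy_test("T1"),
    toy_test("T2", fun = function(target, ctx) stop("broken test")),
    toy_test("T3", result = FALSE),
    toy_test("T4")
  ))
  report <- run_validator(v, three_scan_session(), persist = FALSE)
  expect_equal(vapply(report$results, `[[`, "", "id"),
               c("T1", "T2", "T3", "T4"))
  expect_equal(tidy(report)$has_passed, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(report$summary, list(passed = 2L, failed = 2L))

  empty <- run_validator(qc_validator("E", list()), three_scan_session(),
                         persist = FALSE)
  expect_length(empty$results, 0)
  expect_equal(empty$summary, list(passed = 0L, failed = 0L))
})

test_that("a clean synthetic PET session passes the full PET validator", {
  proj <- selfcheck_project()
  report <- run_validator(pet_session_validator(), proj$sessions$pet_clean,
                          proj, persist = FALSE)
  expect_length(report$results, 9)
  expect_equal(report$summary$failed, 0)
})

test_that("markdown reports carry one section per test with the docstring verbatim", {
  proj <- selfcheck_project()
  report <- run_validator(pet_session_validator(), proj$sessions$pet_clean,
                          proj, persist = FALSE, time = as.POSIXct(0))
  md <- report_to_markdown(report)
  expect_equal(length(gregexpr("\n## ", md)[[1]]), 9)
  for (r in report$results) {
    expect_true(grepl(r$docstring, md, fixed = TRUE))
  }
  expect_match(md, report$code_sha, fixed = TRUE)
  expect_match(md, "pet_clean", fixed = TRUE)

  empty <- run_validator(qc_validator("E", list()), proj$sessions$pet_clean,
                         persist = FALSE)
  expect_false(grepl("\n## ", report_to_markdown(empty)))
})

test_that("report JSON round-trip is the identity and the schema is enforced", {
  proj <- selfcheck_project()
  report <- run_validator(pet_session_validator(), proj$sessions$pet_clean,
                          proj, persist = FALSE, time = as.POSIXct(0))
  back <- report_from_json(report_to_json(report))
  expect_equal(unclass(back), unclass(report))

  # recomputed summary equals stored summary
  expect_equal(sum(!vapply(back$results, `[[`, logical(1), "has_passed")),
               back$summary$failed)

  broken <- jsonlite::fromJSON(report_to_json(report), simplifyVector = FALSE)
  broken$tests[[1]]$has_passed <- NULL
  expect_error(report_from_json(jsonlite::toJSON(broken, auto_unbox = TRUE)),
               "has_passed")
  broken2 <- jsonlite::fromJSON(report_to_json(report), simplifyVector = FALSE)
  broken2$summary <- NULL
  expect_error(report_from_json(jsonlite::toJSON(broken2, auto_unbox = TRUE)),
               "summary")
})

test_that("persisted reports appear as a session resource", {
  root <- withr::local_tempdir()
  proj <- make_project(root, 1, seed = 3)
  sess <- proj$sessions[[1]]
  run_validator(archiving_validator(), sess, proj)
  rdir <- file.path(sess$path, "resources", "ArchivingValidator")
  expect_true(file.exists(file.path(rdir, "report.json")))
  expect_true(file.exists(file.path(rdir, "report.md")))
  expect_true(file.exists(file.path(rdir, "report.html")))
  reloaded <- load_session(sess$path)
  expect_true("ArchivingValidator" %in% names(reloaded$resources))
})

test_that("self_check flags misbehaving and unresolvable fixtures", {
  proj <- selfcheck_project()
  # a test whose failing fixture passes
  lying <- qc_validator("Lying", list(
    qc_test("AlwaysPasses", "Passes everywhere.", "session",
            function(s, ctx) qc_result(TRUE),
            passing = "pet_clean", failing = "pet_weight_low")))
  tab <- self_check(list(lying), proj)
  expect_true(tab$passed_on_passing)
  expect_false(tab$failed_on_failing)
  expect_false(tab$ok)

  # unresolvable fixture
  ghost <- qc_validator("Ghost", list(
    qc_test("GhostFixture", "References a missing fixture.", "session",
            function(s, ctx) qc_result(TRUE),
            passing = "no_such_session", failing = "pet_weight_low")))
  tab2 <- self_check(list(ghost), proj)
  expect_false(tab2$ok)
  expect_match(tab2$note, "unresolvable")

  expect_equal(nrow(self_check(list(), proj)), 0)
})

test_that("self_check is a fixed point over read-only fixtures", {
  proj <- selfcheck_project()
  v <- list(archiving_validator())
  expect_identical(self_check(v, proj), self_check(v, proj))
})
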