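cfg <- qc_config()

test_that("presence-and-membership check accepts allowed values and flags absences", {
  expect_true(metadata_present_and_allowed(
    tweaked_pet_session(), "Radiopharmaceutical", cfg$allowed_tracers)$has_passed)
  expect_true(metadata_present_and_allowed(
    tweaked_pet_session(), "ManufacturerModelName",
    "SIEMENS Biograph64 VG51C")$has_passed)
  # comparison is trim + case-insensitive
  expect_true(metadata_present_and_allowed(
    tweaked_pet_session(Radiopharmaceutical = "  fdg "),
    "Radiopharmaceutical", cfg$allowed_tracers)$has_passed)
  res <- metadata_present_and_allowed(
    tweaked_pet_session(Radiopharmaceutical = NULL),
    "Radiopharmaceutical", cfg$allowed_tracers)
  expect_false(res$has_passed)
  expect_match(jsonlite::toJSON(res$data), "Radiopharmaceutical")
})

test_that("interval check is inclusive and notes parse failures", {
  w <- function(x) metadata_in_interval(tweaked_pet_session(PatientWeight = x),
                                        "PatientWeight", cfg$weight_interval)
  expect_true(w(80)$has_passed)
  expect_true(w(40)$has_passed)
  expect_true(w(150)$has_passed)
  expect_false(w(39.9)$has_passed)
  expect_false(w(150.1)$has_passed)
  bad <- metadata_in_interval(
    tweaked_pet_session(RadionuclideTotalDose = 1.0e8),
    "RadionuclideTotalDose", cfg$dose_interval)
  expect_false(bad$has_passed)
  nn <- w("heavy")
  expect_false(nn$has_passed)
  expect_match(jsonlite::toJSON(nn$data), "not numeric")
})

test_that("interval check is monotone under interval enlargement", {
  weights <- with(list(), {set.seed(11); round(runif(40, 0, 250), 1)})
  for (wt in weights) {
    narrow <- metadata_in_interval(tweaked_pet_session(PatientWeight = wt),
                                   "PatientWeight", interval_spec(40, 150, "kg"))
    wide <- metadata_in_interval(tweaked_pet_session(PatientWeight = wt),
                                 "PatientWeight", interval_spec(30, 200, "kg"))
    if (narrow$has_passed) expect_true(wide$has_passed)
  }
})

test_that("cross-scan consistency compares value sets", {
  root <- withr::local_tempdir()
  mk <- function(id, dates) {
    scans <- lapply(dates, function(d) {
      md <- base_pet_metadata()
      md$StudyDate <- d
      list(metadata = md)
    })
    names(scans) <- sprintf("%04d", seq_along(dates))
    load_session(write_raw_session(root, "ALFA00001", id, scans = scans))
  }
  expect_true(metadata_consistent_across_scans(
    mk("one", "20240501"), cfg$consistency_keys)$has_passed)
  expect_true(metadata_consistent_across_scans(
    mk("three", rep("20240501", 3)), cfg$consistency_keys)$has_passed)
  res <- metadata_consistent_across_scans(
    mk("diverge", c("20240501", "20240502")), cfg$consistency_keys)
  expect_false(res$has_passed)
  expect_equal(res$data[[1]]$key, "StudyDate")
  expect_setequal(unlist(res$data[[1]]$values), c("20240501", "20240502"))
})

test_that("subject id must fully match the configured pattern", {
  ok <- function(id) {
    sess <- tweaked_pet_session(PatientID = id)
    sess$subject_id <- id
    id_matches_pattern(sess, cfg$subject_id_pattern)$has_passed
  }
  # regex oracle
  expect_equal(ok("ALFA12345"), grepl("^[A-Z]+[0-9]{5}$", "ALFA12345"))
  expect_true(ok("ALFA12345"))
  expect_false(ok(""))
  expect_false(ok("ALFA 1234"))
  expect_false(ok("alfa12345"))
  expect_false(ok("xALFA12345x"))
  sess <- tweaked_pet_session(PatientID = "WRONG")
  expect_false(id_matches_pattern(sess, cfg$subject_id_pattern)$has_passed)
  expect_error(suppressWarnings(id_matches_pattern(sess, "(")), "compile")
})

test_that("usable T1 lookup honours quality flags and modality", {
  proj <- selfcheck_project()
  expect_true(has_usable_t1(proj, proj$sessions$pet_clean, cfg)$has_passed)
  # companion exists but its T1 is flagged unusable
  expect_false(has_usable_t1(proj, proj$sessions$pet_no_usable_t1, cfg)$has_passed)
  # subject with no MR session at all
  expect_false(has_usable_t1(proj, proj$sessions$pet_no_usable_t1_flute,
                             cfg)$has_passed)
})

test_that("runnability checks combine tracer, NIfTI and T1 preconditions", {
  proj <- selfcheck_project()
  expect_true(quantification_runnable(proj, proj$sessions$pet_clean_flute,
                                      "centiloid", cfg)$has_passed)
  res <- quantification_runnable(proj, proj$sessions$pet_clean, "centiloid", cfg)
  expect_true(res$has_passed)
  expect_match(unlist(res$data), "not applicable")
  fdg_no_t1 <- quantification_runnable(proj, proj$sessions$pet_no_usable_t1,
                                       "fdg", cfg)
  expect_false(fdg_no_t1$has_passed)
  expect_match(jsonlite::toJSON(fdg_no_t1$data), "T1")
})

test_that("NIfTI conversion check reads the volume, not just the name", {
  root <- withr::local_tempdir()
  sdir <- write_raw_session(root, "ALFA00001", "S1", "MR",
                            list("0001" = list(metadata = base_pet_metadata())))
  sess <- load_session(sdir)
  expect_true(scan_has_nifti(sess$scans[[1]])$has_passed)

  sdir2 <- write_raw_session(root, "ALFA00001", "S2", "MR",
                             list("0001" = list(metadata = base_pet_metadata(),
                                                nifti = FALSE)))
  expect_false(scan_has_nifti(load_session(sdir2)$scans[[1]])$has_passed)

  # truncated gzip volume
  sdir3 <- write_raw_session(root, "ALFA00001", "S3", "MR",
                             list("0001" = list(metadata = base_pet_metadata())))
  nii <- file.path(sdir3, "scans", "0001", "image.nii.gz")
  writeBin(readBin(nii, "raw", 20), nii)
  res <- scan_has_nifti(load_session(sdir3)$scans[[1]])
  expect_false(res$has_passed)
  expect_match(unlist(res$data), "unreadable")
})
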