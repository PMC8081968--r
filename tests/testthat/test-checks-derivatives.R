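fake_resource <- function(files = character(), provenance = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (f in files) {
    target <- file.path(dir, f)
    dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
    writeLines("x", target)
  }
  structure(list(name = basename(dir),
                 files = tibble::tibble(path = sort(files),
                                        size = rep(2L, length(files))),
                 provenance = provenance, path = dir),
            class = "nqc_resource")
}

test_that("manifest check matches globs and tolerates extra files", {
  expect_true(has_correct_items(fake_resource(c("a", "b")), c("a", "b"))$has_passed)
  res <- has_correct_items(fake_resource("a"), c("a", "b"))
  expect_false(res$has_passed)
  expect_equal(unlist(res$data[[1]]$missing), "b")
  expect_true(has_correct_items(fake_resource("stats/aseg.stats"),
                                "stats/aseg.stats")$has_passed)
  expect_true(has_correct_items(fake_resource("stats/aseg.stats"),
                                "stats/*.stats")$has_passed)
  # extra files reported, not failed
  extra <- has_correct_items(fake_resource(c("a", "debug.log")), "a")
  expect_true(extra$has_passed)
  expect_match(jsonlite::toJSON(extra$data), "debug.log")
})

test_that("version check requires exact provenance match", {
  expect_true(has_correct_version(
    fake_resource(provenance = list(software_version = "ASHS 1.0.0")),
    "ASHS 1.0.0")$has_passed)
  expect_false(has_correct_version(
    fake_resource(provenance = list(software_version = "ASHS 0.9")),
    "ASHS 1.0.0")$has_passed)
  absent <- has_correct_version(fake_resource(), "ASHS 1.0.0")
  expect_false(absent$has_passed)
  expect_match(unlist(absent$data), "no provenance")
})

test_that("execution time check subtracts provenance timestamps", {
  prov <- function(secs) list(software_version = "x",
                              started = "2024-05-01T08:00:00Z",
                              finished = format(
                                as.POSIXct("2024-05-01T08:00:00Z",
                                           format = "%Y-%m-%dT%H:%M:%SZ",
                                           tz = "UTC") + secs,
                                "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  ok <- execution_time_within(fake_resource(provenance = prov(600)), 3600)
  expect_true(ok$has_passed)
  expect_equal(ok$data[[1]]$elapsed_seconds, 600)
  slow <- execution_time_within(fake_resource(provenance = prov(7200)), 3600)
  expect_false(slow$has_passed)
  expect_equal(slow$data[[1]]$elapsed_seconds, 7200)
  expect_false(execution_time_within(fake_resource(), 3600)$has_passed)
})

test_that("label volumes are voxel count times header voxel volume", {
  lm <- make_labelmap(c(8, 8, 8), c("1" = 10), seed = 1)
  tab <- compute_label_volumes(lm)
  expect_equal(tab$volume_mm3[tab$label == "1"], 10)

  aniso <- RNifti::asNifti(unclass(lm))
  RNifti::pixdim(aniso) <- c(2, 2, 2)
  expect_equal(compute_label_volumes(aniso)$volume_mm3, 80)
  RNifti::pixdim(aniso) <- c(1, 2, 2.5)
  expect_equal(compute_label_volumes(aniso)$volume_mm3, 50)

  expect_equal(nrow(compute_label_volumes(array(0, c(4, 4, 4)))), 0)
  expect_error(compute_label_volumes(array(0.5, c(2, 2, 2))), "non-integer")
})

test_that("volumes agree with a brute-force voxel counter and conserve totals", {
  set.seed(202)
  for (rep in 1:10) {
    arr <- array(sample(0:4, 16^3, replace = TRUE,
                        prob = c(0.8, 0.05, 0.05, 0.05, 0.05)), c(16, 16, 16))
    tab <- compute_label_volumes(arr)
    # independent triple-loop counter
    counts <- stats::setNames(numeric(5), 0:4)
    for (i in 1:16) for (j in 1:16) for (k in 1:16) {
      key <- as.character(arr[i, j, k])
      counts[key] <- counts[key] + 1
    }
    for (lab in tab$label) {
      expect_identical(tab$volume_mm3[tab$label == lab],
                       unname(counts[lab]))
    }
    expect_identical(sum(tab$volume_mm3) + unname(counts["0"]), 16^3)
  }
})

test_that("subfield completeness lists absent labels", {
  lm <- make_labelmap(c(12, 12, 12), c("1" = 30, "2" = 30, "4" = 30,
                                       "5" = 30), seed = 2)
  expect_true(has_all_subfields(lm, c(1, 2, 4, 5))$has_passed)
  res <- has_all_subfields(lm, 1:5)
  expect_false(res$has_passed)
  expect_equal(unlist(res$data[[1]]$absent_labels), 3)
  expect_true(has_all_subfields(lm, integer(0))$has_passed)
})

test_that("safety-interval check is inclusive and ignores unkeyed regions", {
  vols <- tibble::tibble(label = c("1", "2"), volume_mm3 = c(500, 40))
  iv <- list("1" = interval_spec(50, 5000, "mm3"))
  expect_true(volumes_within_intervals(vols, iv)$has_passed)
  iv2 <- list("2" = interval_spec(50, 5000, "mm3"))
  res <- volumes_within_intervals(vols, iv2)
  expect_false(res$has_passed)
  expect_equal(res$data[[1]]$region, "2")
  expect_true(volumes_within_intervals(vols, list())$has_passed)
  # fractions need the total volume
  frac <- list("1" = interval_spec(0.02, 0.6, "fraction"))
  expect_true(volumes_within_intervals(vols, frac,
                                       total_volume = 5000)$has_passed)
  expect_error(volumes_within_intervals(vols, frac), "total_volume")
})

test_that("aseg.stats parsing extracts StructName and Volume_mm3", {
  f <- withr::local_tempfile(fileext = ".stats")
  writeLines(c(
    "# Title Segmentation Statistics",
    "# ColHeaders  Index SegId NVoxels Volume_mm3 StructName normMean",
    "  1   4  7500  7500.5  Left-Lateral-Ventricle  25.1",
    "  2  17  4200  4199.9  Left-Hippocampus  80.0",
    "  3  18  1700  1700.0  Left-Amygdala  85.5"), f)
  tab <- parse_aseg_stats(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$volume_mm3[tab$label == "Left-Hippocampus"], 4199.9)
  expect_equal(tab$volume_mm3[tab$label == "Left-Lateral-Ventricle"], 7500.5)

  hdr_only <- withr::local_tempfile(fileext = ".stats")
  writeLines(c("# Title x", "# ColHeaders Index StructName Volume_mm3"),
             hdr_only)
  expect_equal(nrow(parse_aseg_stats(hdr_only)), 0)

  bad <- withr::local_tempfile(fileext = ".stats")
  writeLines(c("# ColHeaders Index StructName NVoxels", "1 Thing 5"), bad)
  expect_error(parse_aseg_stats(bad), "Volume_mm3")

  # row count preserved exactly (line-count oracle)
  gen <- withr::local_tempfile(fileext = ".stats")
  neuroqc:::write_aseg_stats(gen, seed = 5)
  body_lines <- sum(!grepl("^#", readLines(gen)))
  expect_equal(nrow(parse_aseg_stats(gen)), body_lines)
})
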