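# Shared fixtures, built once per test run. The self-check project is
# comparatively expensive (~30 sessions with NIfTI volumes), so it is
# cached; tests that mutate a project build their own.

selfcheck_project <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_selfcheck_project(
        file.path(tempdir(), "neuroqc-selfcheck-fixture"), seed = 42)
    }
    cache
  }
})

# Write a session directory by hand (independent of make_session), for
# ad-hoc scan layouts.
write_raw_session <- function(root, subject_id, session_id, modality = "PET",
                              scans = list()) {
  sess_dir <- file.path(root, subject_id, session_id)
  dir.create(sess_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(session_id = session_id, subject_id = subject_id,
                            modality = modality),
                       file.path(sess_dir, "session.json"), auto_unbox = TRUE)
  for (scan_id in names(scans)) {
    sdir <- file.path(sess_dir, "scans", scan_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    spec <- scans[[scan_id]]
    jsonlite::write_json(spec$metadata %||% list(PatientID = subject_id),
                         file.path(sdir, "image.json"), auto_unbox = TRUE)
    if (isTRUE(spec$nifti %||% TRUE)) {
      RNifti::writeNifti(make_phantom(c(8, 8, 8), seed = 1),
                         file.path(sdir, "image.nii.gz"))
    }
  }
  sess_dir
}

base_pet_metadata <- function(subject_id = "ALFA00001") {
  list(PatientID = subject_id, PatientWeight = 75,
       Radiopharmaceutical = "FDG", RadionuclideTotalDose = 2.0e8,
       Manufacturer = "SIEMENS",
       ManufacturerModelName = "SIEMENS Biograph64 VG51C",
       SeriesDescription = "PET WB AC", StudyDate = "20240501",
       Modality = "PT")
}

# A loaded one-scan PET session whose metadata can be tweaked in memory.
tweaked_pet_session <- local({
  template <- NULL
  function(...) {
    if (is.null(template)) {
      root <- file.path(tempdir(), "neuroqc-tweak-fixture")
      write_raw_session(root, "ALFA00001", "pet_template",
                        scans = list("0001" = list(metadata = base_pet_metadata())))
      template <<- load_session(file.path(root, "ALFA00001", "pet_template"))
    }
    sess <- template
    overrides <- list(...)
    for (key in names(overrides)) {
      sess$scans[[1]]$metadata[[key]] <- overrides[[key]]
    }
    sess
  }
})

failing_ids <- function(report) {
  td <- tidy(report)
  td$test_id[!td$has_passed]
}
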