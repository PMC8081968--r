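get_resource <- function(session, name) {
  session$resources[[name]]
}

require_resource <- function(session, name) {
  res <- get_resource(session, name)
  if (is.null(res)) {
    abort(sprintf("session '%s' has no '%s' resource", session$session_id, name))
  }
  res
}

pipeline_labelmap <- function(session, pipe, config) {
  res <- require_resource(session, pipe)
  lm <- file.path(res$path, config$pipelines[[pipe]]$labelmap)
  if (!file.exists(lm)) {
    abort(sprintf("resource '%s' of session '%s' has no label map '%s'",
                  pipe, session$session_id, config$pipelines[[pipe]]$labelmap))
  }
  lm
}

snapshot_qc_test <- function(pipe, failing) {
  qc_test(
    id = paste0(sub("FREESURFER6", "FreeSurfer6", pipe), "Snapshot"),
    docstring = sprintf(
      "Generates a snapshot of the %s segmentation overlaid on the anatomical scan and attaches it to the validation report. Passes if the snapshot file is produced and non-empty.",
      pipe),
    level = "session",
    run = function(session, ctx) {
      lm <- pipeline_labelmap(session, pipe, ctx$config)
      bg <- NULL
      if (length(session$scans)) {
        scan <- session$scans[[1]]
        nii <- grep("\\.nii(\\.gz)?$", scan$files, value = TRUE)
        if (length(nii)) bg <- file.path(scan$path, nii[1])
      }
      fname <- sprintf("%s_snapshot.png", tolower(pipe))
      out <- file.path(ctx$out_dir, fname)
      plot_segment(lm, bg = bg, out_path = out,
                   spec = snapshot_spec(planes = "axial", n_slices = 3,
                                        rowsize = 3))
      ok <- file.exists(out) && file.size(out) > 0
      qc_result(ok, list(fname))
    },
    passing = "mr_clean", failing = failing
  )
}

manifest_qc_test <- function(pipe) {
  qc_test(
    id = "HasCorrectItems",
    docstring = sprintf(
      "Checks that the list of files generated by the %s pipeline matches the expected manifest. Missing expected items fail the check; unexpected extra files are only reported.",
      pipe),
    level = "session",
    run = function(session, ctx) {
      has_correct_items(require_resource(session, pipe),
                        ctx$config$pipelines[[pipe]]$manifest)
    },
    passing = "mr_clean", failing = "mr_missing_manifest_file"
  )
}

version_qc_test <- function(pipe, label) {
  qc_test(
    id = sprintf("HasCorrect%sVersion", label),
    docstring = sprintf(
      "Controls that the %s outputs were produced by the expected software version, as recorded in the resource's provenance.",
      pipe),
    level = "session",
    run = function(session, ctx) {
      has_correct_version(require_resource(session, pipe),
                          ctx$config$pipelines[[pipe]]$version)
    },
    passing = "mr_clean", failing = "mr_wrong_version"
  )
}

exec_time_qc_test <- function(pipe, id) {
  qc_test(
    id = id,
    docstring = sprintf(
      "Checks whether the %s pipeline took longer than the configured threshold; the elapsed time is recorded in the result data.",
      pipe),
    level = "session",
    run = function(session, ctx) {
      execution_time_within(require_resource(session, pipe),
                            ctx$config$pipelines[[pipe]]$max_seconds)
    },
    passing = "mr_clean", failing = "mr_overlong_execution"
  )
}

#' The shipped PET session validator
#'
#' Nine tests run on every incoming PET session, in this order:
#' IsTracerCorrect, IsSeriesDescriptionConsistent,
#' IsScannerVersionCorrect, IsSubjectWeightConsistent,
#' IsTracerDoseConsistent, IsSubjectIdCorrect, HasUsableT1,
#' IsCentiloidRunnable, IsFDGQuantificationRunnable.
#'
#' @return A [qc_validator()].
#' @export
pet_session_validator <- function() {
  qc_validator("PetSessionValidator", list(
    qc_test("IsTracerCorrect",
            "Checks that the tracer information (Radiopharmaceutical) is correctly registered in the DICOM-derived metadata of every scan and names one of the allowed radiopharmaceuticals.",
            "session",
            function(session, ctx) {
              metadata_present_and_allowed(session, "Radiopharmaceutical",
                                           ctx$config$allowed_tracers)
            },
            passing = "pet_clean", failing = "pet_missing_tracer"),
    qc_test("IsSeriesDescriptionConsistent",
            "Makes sure that metadata are consistent across the session: each configured key (patient id, study date, manufacturer, scanner model) takes a single value over all scans.",
            "session",
            function(session, ctx) {
              metadata_consistent_across_scans(session,
                                               ctx$config$consistency_keys)
            },
            passing = "pet_clean", failing = "pet_inconsistent_metadata"),
    qc_test("IsScannerVersionCorrect",
            "Checks in the DICOM-derived metadata that the scanner model matches the expected PET scanner (by default, SIEMENS Biograph64 VG51C).",
            "session",
            function(session, ctx) {
              metadata_present_and_allowed(session, "ManufacturerModelName",
                                           ctx$config$expected_pet_scanner)
            },
            passing = "pet_clean", failing = "pet_bad_scanner"),
    qc_test("IsSubjectWeightConsistent",
            "Controls that the subject weight registered at acquisition falls inside the target interval (by default, between 40 and 150 kg, inclusive).",
            "session",
            function(session, ctx) {
              metadata_in_interval(session, "PatientWeight",
                                   ctx$config$weight_interval)
            },
            passing = "pet_clean", failing = "pet_weight_low"),
    qc_test("IsTracerDoseConsistent",
            "Controls that the injected tracer dose registered at acquisition falls inside the target interval (by default, between 1.5e8 and 3.5e8 Bq, inclusive).",
            "session",
            function(session, ctx) {
              metadata_in_interval(session, "RadionuclideTotalDose",
                                   ctx$config$dose_interval)
            },
            passing = "pet_clean", failing = "pet_dose_low"),
    qc_test("IsSubjectIdCorrect",
            "Ensures the subject's identifier has the right format: the session's subject id and every scan's PatientID must fully match the configured pattern.",
            "session",
            function(session, ctx) {
              id_matches_pattern(session, ctx$config$subject_id_pattern)
            },
            passing = "pet_clean", failing = "pet_bad_subject_id"),
    qc_test("HasUsableT1",
            "Checks whether the subject has a valid T1-weighted image available: some MR session of the same subject must contain a T1-weighted scan flagged usable.",
            "session",
            function(session, ctx) {
              has_usable_t1(ctx$project, session, ctx$config)
            },
            passing = "pet_clean", failing = "pet_no_usable_t1"),
    qc_test("IsCentiloidRunnable",
            "Assesses whether the data are suited for execution of the Centiloid amyloid quantification pipeline: a flutemetamol session with a converted PET NIfTI and a usable T1-weighted image. Sessions with another tracer are out of scope and pass with a note.",
            "session",
            function(session, ctx) {
              quantification_runnable(ctx$project, session, "centiloid",
                                      ctx$config)
            },
            passing = "pet_clean_flute", failing = "pet_no_usable_t1_flute"),
    qc_test("IsFDGQuantificationRunnable",
            "Assesses whether the data are suited for execution of the FDG quantification pipeline: an FDG session with a converted PET NIfTI and a usable T1-weighted image. Sessions with another tracer are out of scope and pass with a note.",
            "session",
            function(session, ctx) {
              quantification_runnable(ctx$project, session, "fdg", ctx$config)
            },
            passing = "pet_clean", failing = "pet_no_usable_t1")
  ))
}

#' The shipped MR archiving validator
#'
#' Run on every archived MR session: HasNifti (scan level; a failing scan
#' is downgraded to questionable), IsSubjectIdCorrect,
#' IsScannerVersionCorrect (MR scanner model),
#' IsSeriesDescriptionConsistent.
#'
#' @return A [qc_validator()].
#' @export
archiving_validator <- function() {
  qc_validator("ArchivingValidator", list(
    qc_test("HasNifti",
            "Checks, scan by scan, that the acquired DICOM files have been converted to NIfTI: every scan must carry at least one readable NIfTI volume.",
            "scan",
            function(scan, ctx) scan_has_nifti(scan),
            passing = "mr_clean", failing = "mr_missing_nifti",
            on_fail_flag = "questionable"),
    qc_test("IsSubjectIdCorrect",
            "Ensures the subject's identifier has the right format: the session's subject id and every scan's PatientID must fully match the configured pattern.",
            "session",
            function(session, ctx) {
              id_matches_pattern(session, ctx$config$subject_id_pattern)
            },
            passing = "mr_clean", failing = "mr_bad_subject_id"),
    qc_test("IsScannerVersionCorrect",
            "Checks in the DICOM-derived metadata that the scanner model matches the expected MR scanner (by default, Philips Ingenia CX).",
            "session",
            function(session, ctx) {
              metadata_present_and_allowed(session, "ManufacturerModelName",
                                           ctx$config$expected_mr_scanner)
            },
            passing = "mr_clean", failing = "mr_bad_scanner"),
    qc_test("IsSeriesDescriptionConsistent",
            "Makes sure that metadata are consistent across the session: each configured key takes a single value over all scans.",
            "session",
            function(session, ctx) {
              metadata_consistent_across_scans(session,
                                               ctx$config$consistency_keys)
            },
            passing = "mr_clean", failing = "mr_inconsistent_metadata")
  ))
}

#' The shipped hippocampal-subfield (ASHS) validator
#'
#' Run after every ASHS execution over an MR session: HasAllSubfields,
#' HasCorrectASHSVersion, HasCorrectItems, HasNormalSubfieldVolumes,
#' ASHSSnapshot.
#'
#' @return A [qc_validator()].
#' @export
ashs_validator <- function() {
  qc_validator("ASHSValidator", list(
    qc_test("HasAllSubfields",
            "Makes sure that all expected hippocampal subfields appear in the final ASHS segmentation: every expected label must be present with at least one voxel.",
            "session",
            function(session, ctx) {
              has_all_subfields(pipeline_labelmap(session, "ASHS", ctx$config),
                                ctx$config$pipelines$ASHS$expected_labels)
            },
            passing = "mr_clean", failing = "mr_missing_subfield"),
    version_qc_test("ASHS", "ASHS"),
    manifest_qc_test("ASHS"),
    qc_test("HasNormalSubfieldVolumes",
            "Assesses whether the resulting subfield volumes fall inside the configured safety intervals (inclusive, in cubic millimeters).",
            "session",
            function(session, ctx) {
              lm <- pipeline_labelmap(session, "ASHS", ctx$config)
              volumes_within_intervals(
                compute_label_volumes(lm),
                ctx$config$pipelines$ASHS$volume_intervals)
            },
            passing = "mr_clean", failing = "mr_abnormal_volume"),
    snapshot_qc_test("ASHS", failing = "mr_missing_labelmap")
  ))
}

#' The shipped tissue-segmentation (SPM12) validator
#'
#' Run after every SPM12 segmentation: HasCorrectItems,
#' HasCorrectSPM12Version, SPM12SegmentExecutionTime, HasNormalVolumes
#' (global gray/white matter as fractions of image volume), SPM12Snapshot.
#'
#' @return A [qc_validator()].
#' @export
spm12_validator <- function() {
  qc_validator("SPM12Validator", list(
    manifest_qc_test("SPM12"),
    version_qc_test("SPM12", "SPM12"),
    exec_time_qc_test("SPM12", "SPM12SegmentExecutionTime"),
    qc_test("HasNormalVolumes",
            "Assesses whether the global gray and white matter volumes fall inside predefined target intervals, expressed as fractions of the total image volume.",
            "session",
            function(session, ctx) {
              lm <- as_labelmap(pipeline_labelmap(session, "SPM12", ctx$config))
              total <- prod(dim(unclass(lm))) * voxel_volume_mm3(lm)
              volumes_within_intervals(
                compute_label_volumes(lm),
                ctx$config$pipelines$SPM12$volume_intervals,
                total_volume = total)
            },
            passing = "mr_clean", failing = "mr_abnormal_volume"),
    snapshot_qc_test("SPM12", failing = "mr_missing_labelmap")
  ))
}

#' The shipped FreeSurfer validator
#' @return A [qc_validator()].
#' @export
freesurfer6_validator <- function() {
  qc_validator("FreeSurfer6Validator", list(
    manifest_qc_test("FREESURFER6"),
    version_qc_test("FREESURFER6", "FreeSurfer6"),
    exec_time_qc_test("FREESURFER6", "FreeSurfer6ExecutionTime"),
    snapshot_qc_test("FREESURFER6", failing = "mr_missing_labelmap")
  ))
}

#' The shipped DTIFIT validator
#' @return A [qc_validator()].
#' @export
dtifit_validator <- function() {
  qc_validator("DTIFITValidator", list(
    manifest_qc_test("DTIFIT"),
    version_qc_test("DTIFIT", "DTIFIT"),
    snapshot_qc_test("DTIFIT", failing = "mr_missing_labelmap")
  ))
}

#' The shipped ANTs registration validator
#' @return A [qc_validator()].
#' @export
ants_validator <- function() {
  qc_validator("ANTSValidator", list(
    manifest_qc_test("ANTS"),
    version_qc_test("ANTS", "ANTS"),
    snapshot_qc_test("ANTS", failing = "mr_missing_labelmap")
  ))
}

#' The shipped validator registry
#'
#' @return A named list of every shipped [qc_validator()], keyed by
#'   validator name.
#' @export
qc_registry <- function() {
  vs <- list(pet_session_validator(), archiving_validator(), ashs_validator(),
             spm12_validator(), freesurfer6_validator(), dtifit_validator(),
             ants_validator())
  stats::setNames(vs, vapply(vs, `[[`, "", "name"))
}
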