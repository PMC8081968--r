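#' An inclusive numeric acceptance interval
#'
#' @param lower,upper Interval endpoints (inclusive at both ends: physical
#'   readings exactly at a bound are acceptable).
#' @param unit Unit label recorded for reporting (e.g. `"kg"`, `"Bq"`,
#'   `"mm3"`, `"fraction"`).
#' @return A list of class `qc_interval`.
#' @export
interval_spec <- function(lower, upper, unit = "") {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  structure(list(lower = lower, upper = upper, unit = unit),
            class = "qc_interval")
}

default_pipeline_config <- function() {
  list(
    ASHS = list(
      version = "ASHS 1.0.0",
      manifest = c("stats/volumes.csv", "logs/ashs.log"),
      labelmap = "labelmap.nii.gz",
      expected_labels = 1:5,
      # Hippocampal-subfield safety intervals, mm3. Broad literature-plausible
      # ranges: site-calibrate me.
      volume_intervals = stats::setNames(
        lapply(1:5, function(i) interval_spec(50, 5000, "mm3")),
        as.character(1:5)),
      max_seconds = 4 * 3600
    ),
    SPM12 = list(
      version = "SPM12 r7771",
      manifest = c("stats/volumes.csv", "logs/spm12.log"),
      labelmap = "labelmap.nii.gz",
      # Global tissue classes as fraction of total image volume
      # (1 = gray matter, 2 = white matter). Site-calibrate me.
      volume_intervals = list(
        "1" = interval_spec(0.02, 0.6, "fraction"),
        "2" = interval_spec(0.01, 0.5, "fraction")),
      max_seconds = 3600
    ),
    FREESURFER6 = list(
      version = "FreeSurfer 6.0.0",
      manifest = c("stats/aseg.stats", "logs/recon-all.log"),
      labelmap = "labelmap.nii.gz",
      max_seconds = 24 * 3600
    ),
    DTIFIT = list(
      version = "FSL 6.0.4",
      manifest = c("logs/dtifit.log"),
      labelmap = "labelmap.nii.gz",
      max_seconds = 3600
    ),
    ANTS = list(
      version = "ANTs 2.3.4",
      manifest = c("logs/ants.log"),
      labelmap = "labelmap.nii.gz",
      max_seconds = 7200
    )
  )
}

#' Quality-control configuration
#'
#' All thresholds, patterns and string expectations used by the shipped
#' checks live in one configuration object. Defaults mirror a single-site
#' PET/MR installation (Siemens Biograph64 PET, Philips Ingenia MR, FDG and
#' flutemetamol tracers) and are meant to be site-calibrated.
#'
#' @param file Optional JSON configuration file; top-level keys override the
#'   shipped defaults. Intervals are given as `[lower, upper]` pairs.
#' @param ... Named overrides applied after `file`.
#' @return A list of class `qc_config` with fields `allowed_tracers`,
#'   `expected_pet_scanner`, `expected_mr_scanner`, `subject_id_pattern`,
#'   `consistency_keys`, `weight_interval` (kg), `dose_interval` (Bq),
#'   `t1_designation` (substring of SeriesDescription marking a
#'   T1-weighted scan), and per-pipeline blocks under `pipelines`
#'   (expected software version, file manifest, label-map file name,
#'   expected segmentation labels, volume safety intervals, maximum
#'   execution time in seconds).
#' @export
qc_config <- function(file = NULL, ...) {
  cfg <- list(
    allowed_tracers = c("FDG", "FLUTEMETAMOL"),
    expected_pet_scanner = "SIEMENS Biograph64 VG51C",
    expected_mr_scanner = "Philips Ingenia CX",
    subject_id_pattern = "^[A-Z]+[0-9]{5}$",
    consistency_keys = c("PatientID", "StudyDate", "Manufacturer",
                         "ManufacturerModelName"),
    weight_interval = interval_spec(40, 150, "kg"),
    dose_interval = interval_spec(1.5e8, 3.5e8, "Bq"),
    t1_designation = "T1",
    pipelines = default_pipeline_config()
  )
  if (!is.null(file)) {
    user <- read_json_file(file)
    for (key in c("weight_interval", "dose_interval")) {
      if (!is.null(user[[key]])) {
        v <- unlist(user[[key]])
        user[[key]] <- interval_spec(v[1], v[2], cfg[[key]]$unit)
      }
    }
    for (key in c("allowed_tracers", "consistency_keys")) {
      if (!is.null(user[[key]])) user[[key]] <- unlist(user[[key]])
    }
    cfg <- utils::modifyList(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (inherits(try(grepl(cfg$subject_id_pattern, "x"), silent = TRUE), "try-error")) {
    abort("subject_id_pattern does not compile")
  }
  structure(cfg, class = "qc_config")
}
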