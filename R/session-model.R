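#' @section Project layout:
#' A project is a plain directory tree mirroring the Project > Subject >
#' Session > Scan/Resource hierarchy common to imaging databases:
#'
#' ```
#' <root>/<subject>/<session>/session.json
#' <root>/<subject>/<session>/scans/<scan_id>/image.nii.gz
#' <root>/<subject>/<session>/scans/<scan_id>/image.json      (metadata sidecar)
#' <root>/<subject>/<session>/scans/<scan_id>/quality_flag    (optional)
#' <root>/<subject>/<session>/resources/<NAME>/...            (pipeline outputs)
#' <root>/<subject>/<session>/resources/<NAME>/provenance.json (optional)
#' ```
#'
#' Metadata sidecars are JSON files carrying DICOM-derived keys
#' (PatientID, PatientWeight in kg, Radiopharmaceutical,
#' RadionuclideTotalDose in Bq, Manufacturer, ManufacturerModelName,
#' SeriesDescription, StudyDate, Modality). A DICOM ingestion adapter is a
#' documented extension point; the checks only consume these keys.
#' @name project-layout
#' @keywords internal
NULL

QUALITY_FLAGS <- c("usable", "questionable", "unusable")

NUMERIC_METADATA_KEYS <- c("PatientWeight", "RadionuclideTotalDose")

new_scan <- function(scan_id, metadata, quality_flag, files, path) {
  structure(
    list(scan_id = scan_id, metadata = metadata, quality_flag = quality_flag,
         files = files, path = path),
    class = "nqc_scan"
  )
}

new_resource <- function(name, files, provenance, path) {
  structure(
    list(name = name, files = files, provenance = provenance, path = path),
    class = "nqc_resource"
  )
}

validate_metadata <- function(metadata, file) {
  for (key in NUMERIC_METADATA_KEYS) {
    if (!is.null(metadata[[key]])) {
      val <- suppressWarnings(as.numeric(metadata[[key]]))
      if (is.na(val) || !is.finite(val) || val < 0) {
        abort(sprintf(
          "invalid metadata in '%s': %s = '%s' must be a finite non-negative number",
          file, key, as.character(metadata[[key]])))
      }
    }
  }
  metadata
}

load_scan <- function(path) {
  scan_id <- basename(path)
  sidecars <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  metadata <- list()
  for (sc in sidecars) {
    md <- tryCatch(read_json_file(sc), error = function(e) {
      abort(sprintf("unparseable metadata sidecar '%s': %s", sc, conditionMessage(e)))
    })
    metadata <- utils::modifyList(metadata, validate_metadata(md, sc))
  }
  flag_file <- file.path(path, "quality_flag")
  flag <- "usable"
  if (file.exists(flag_file)) {
    flag <- trimws(readLines(flag_file, warn = FALSE)[1])
    if (!flag %in% QUALITY_FLAGS) {
      abort(sprintf("invalid quality flag '%s' in '%s'", flag, flag_file))
    }
  }
  files <- setdiff(list.files(path, recursive = TRUE), "quality_flag")
  new_scan(scan_id, metadata, flag, sort(files), path)
}

load_resource <- function(path) {
  files <- list.files(path, recursive = TRUE)
  prov <- NULL
  prov_file <- file.path(path, "provenance.json")
  if (file.exists(prov_file)) {
    prov <- read_json_file(prov_file)
    if (!is.null(prov$started) && !is.null(prov$finished) &&
        parse_time(prov$finished) < parse_time(prov$started)) {
      abort(sprintf("provenance in '%s': finished precedes started", prov_file))
    }
  }
  sizes <- file.size(file.path(path, files))
  new_resource(basename(path),
               tibble(path = sort(files), size = sizes[order(files)]),
               prov, path)
}

parse_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Load one imaging session from disk
#'
#' Reads a session directory (see the package's project layout): the
#' `session.json` descriptor, every scan with its JSON metadata sidecar and
#' quality flag, and every derivative resource with its file list and
#' optional provenance record. Scans are ordered lexicographically by scan
#' identifier so reports are deterministic.
#'
#' @param path Session directory.
#' @return An object of class `nqc_session` with fields `session_id`,
#'   `subject_id`, `modality` (`"MR"` or `"PET"`), `scans` (named list of
#'   `nqc_scan`), `resources` (named list of `nqc_resource`) and `path`.
#' @export
load_session <- function(path) {
  desc_file <- file.path(path, "session.json")
  if (!file.exists(desc_file)) {
    abort(sprintf("'%s' is not a session directory (no session.json)", path))
  }
  desc <- read_json_file(desc_file)
  for (field in c("session_id", "subject_id", "modality")) {
    if (is.null(desc[[field]])) {
      abort(sprintf("session descriptor '%s' lacks field '%s'", desc_file, field))
    }
  }
  if (!desc$modality %in% c("MR", "PET")) {
    abort(sprintf("unknown modality '%s' in '%s'", desc$modality, desc_file))
  }
  scan_dirs <- list.dirs(file.path(path, "scans"), recursive = FALSE)
  scans <- lapply(sort(scan_dirs), load_scan)
  names(scans) <- vapply(scans, `[[`, "", "scan_id")
  if (anyDuplicated(names(scans))) {
    abort(sprintf("duplicate scan identifiers in '%s'", path))
  }
  res_dirs <- list.dirs(file.path(path, "resources"), recursive = FALSE)
  resources <- lapply(sort(res_dirs), load_resource)
  names(resources) <- vapply(resources, `[[`, "", "name")
  structure(
    list(session_id = desc$session_id, subject_id = desc$subject_id,
         modality = desc$modality, scans = scans, resources = resources,
         path = normalizePath(path)),
    class = "nqc_session"
  )
}

#' Load a whole imaging project
#'
#' Walks `<root>/<subject>/<session>` and loads every layout-conformant
#' session. Malformed session directories are skipped but reported as
#' warnings collected on the returned object, never silently dropped.
#'
#' @param root Project root directory.
#' @return An object of class `nqc_project` with fields `root`, `sessions`
#'   (named list of [load_session()] results keyed by session id),
#'   `subjects` (character vector) and `warnings` (character vector of
#'   skipped directories with reasons).
#' @export
load_project <- function(root) {
  if (!dir.exists(root)) {
    abort(sprintf("project root '%s' does not exist", root))
  }
  warnings <- character(0)
  sessions <- list()
  for (subj_dir in sort(list.dirs(root, recursive = FALSE))) {
    for (sess_dir in sort(list.dirs(subj_dir, recursive = FALSE))) {
      if (!file.exists(file.path(sess_dir, "session.json"))) {
        warnings <- c(warnings, sprintf(
          "skipped '%s': not a session directory (no session.json)", sess_dir))
        next
      }
      sess <- tryCatch(load_session(sess_dir), error = function(e) {
        warnings <<- c(warnings, sprintf("skipped '%s': %s", sess_dir,
                                         conditionMessage(e)))
        NULL
      })
      if (!is.null(sess)) sessions[[sess$session_id]] <- sess
    }
  }
  # Non-subject clutter directly under root (files are ignored by design).
  if (anyDuplicated(names(sessions))) {
    abort(sprintf("duplicate session identifiers under '%s'", root))
  }
  for (w in warnings) warn(w)
  structure(
    list(root = normalizePath(root), sessions = sessions,
         subjects = sort(unique(vapply(sessions, `[[`, "", "subject_id"))),
         warnings = warnings),
    class = "nqc_project"
  )
}

#' Set a scan's quality flag
#'
#' Quality flags record per-scan usability (`usable`, `questionable`,
#' `unusable`). Automated test failures may only *downgrade* a flag; a human
#' override in either direction requires `force = TRUE`. The flag is
#' persisted next to the scan's files.
#'
#' @param scan An `nqc_scan`.
#' @param new_flag One of `"usable"`, `"questionable"`, `"unusable"`.
#' @param force Allow upgrades (manual override). Default `FALSE`: an
#'   upgrade attempt is rejected with a warning and the scan is returned
#'   unchanged.
#' @return The scan with its updated (and persisted) flag.
#' @export
set_quality_flag <- function(scan, new_flag, force = FALSE) {
  stopifnot(inherits(scan, "nqc_scan"))
  new_flag <- match.arg(new_flag, QUALITY_FLAGS)
  old_rank <- match(scan$quality_flag, QUALITY_FLAGS)
  new_rank <- match(new_flag, QUALITY_FLAGS)
  if (new_rank < old_rank && !isTRUE(force)) {
    warn(sprintf(
      "rejected quality flag upgrade %s -> %s for scan '%s' (use force = TRUE to override)",
      scan$quality_flag, new_flag, scan$scan_id))
    return(scan)
  }
  scan$quality_flag <- new_flag
  if (!is.null(scan$path) && dir.exists(scan$path)) {
    writeLines(new_flag, file.path(scan$path, "quality_flag"))
  }
  scan
}

#' @export
print.nqc_session <- function(x, ...) {
  cat(sprintf("<%s session %s / subject %s: %d scan(s), %d resource(s)>\n",
              x$modality, x$session_id, x$subject_id,
              length(x$scans), length(x$resources)))
  invisible(x)
}

#' @export
print.nqc_project <- function(x, ...) {
  cat(sprintf("<imaging project %s: %d session(s), %d subject(s)>\n",
              x$root, length(x$sessions), length(x$subjects)))
  invisible(x)
}

# Sessions of one subject, optionally restricted by modality.
subject_sessions <- function(project, subject_id, modality = NULL) {
  keep <- vapply(project$sessions, function(s) {
    s$subject_id == subject_id && (is.null(modality) || s$modality == modality)
  }, logical(1))
  project$sessions[keep]
}
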