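norm_str <- function(x) toupper(trimws(as.character(x)))

scan_meta <- function(scan, key) {
  val <- scan$metadata[[key]]
  if (is.null(val)) NULL else as.character(val)
}

#' Metadata presence-and-membership check
#'
#' Passes iff every scan of the session carries the metadata key and its
#' value is one of the allowed strings (compared case-insensitively after
#' whitespace trimming; raw values are echoed in the detail payload).
#' Absence of the key is a failure, not an error. This is the generic
#' primitive behind the tracer and scanner-model checks.
#'
#' @param session An `nqc_session`.
#' @param key Metadata key (e.g. `"Radiopharmaceutical"`).
#' @param allowed Character vector of acceptable values.
#' @return A [qc_result()].
#' @export
metadata_present_and_allowed <- function(session, key, allowed) {
  bad <- list()
  for (scan in session$scans) {
    val <- scan_meta(scan, key)
    if (is.null(val)) {
      bad[[length(bad) + 1L]] <- list(scan = scan$scan_id, key = key,
                                      problem = "missing")
    } else if (!norm_str(val) %in% norm_str(allowed)) {
      bad[[length(bad) + 1L]] <- list(scan = scan$scan_id, key = key,
                                      value = val, problem = "not allowed")
    }
  }
  qc_result(length(bad) == 0L && length(session$scans) > 0L,
            if (length(bad)) bad else
              list(sprintf("%s valid on all %d scan(s)", key,
                           length(session$scans))))
}

#' Numeric metadata interval check
#'
#' Passes iff the key is present on every scan, parses as a number and
#' lies inside the closed interval (both endpoints inclusive: a physical
#' reading exactly at a bound is acceptable). Used for subject weight
#' (kg) and injected tracer dose (Bq) gates.
#'
#' @param session An `nqc_session`.
#' @param key Metadata key (e.g. `"PatientWeight"`).
#' @param interval An [interval_spec()].
#' @return A [qc_result()].
#' @export
metadata_in_interval <- function(session, key, interval) {
  stopifnot(inherits(interval, "qc_interval"))
  bad <- list()
  seen <- list()
  for (scan in session$scans) {
    raw <- scan_meta(scan, key)
    if (is.null(raw)) {
      bad[[length(bad) + 1L]] <- list(scan = scan$scan_id, key = key,
                                      problem = "missing")
      next
    }
    val <- suppressWarnings(as.numeric(raw))
    if (is.na(val)) {
      bad[[length(bad) + 1L]] <- list(scan = scan$scan_id, key = key,
                                      value = raw,
                                      problem = "not numeric")
    } else if (val < interval$lower || val > interval$upper) {
      bad[[length(bad) + 1L]] <- list(
        scan = scan$scan_id, key = key, value = val,
        interval = sprintf("[%g, %g] %s", interval$lower, interval$upper,
                           interval$unit))
    } else {
      seen[[length(seen) + 1L]] <- list(scan = scan$scan_id, key = key,
                                        value = val, unit = interval$unit)
    }
  }
  qc_result(length(bad) == 0L && length(session$scans) > 0L,
            if (length(bad)) bad else seen)
}

#' Cross-scan metadata consistency check
#'
#' Passes iff each key takes a single value across all scans of the
#' session (vacuously true for a one-scan session). The detail payload
#' lists divergent keys with their observed value sets.
#'
#' @param session An `nqc_session`.
#' @param keys Character vector of metadata keys to compare.
#' @return A [qc_result()].
#' @export
metadata_consistent_across_scans <- function(session, keys) {
  divergent <- list()
  for (key in keys) {
    vals <- unique(vapply(session$scans, function(s) {
      scan_meta(s, key) %||% NA_character_
    }, character(1)))
    if (length(vals) > 1L) {
      divergent[[length(divergent) + 1L]] <-
        list(key = key, values = as.list(sort(vals, na.last = TRUE)))
    }
  }
  qc_result(length(divergent) == 0L,
            if (length(divergent)) divergent else
              list(sprintf("%d key(s) consistent across %d scan(s)",
                           length(keys), length(session$scans))))
}

#' Subject identifier format check
#'
#' Passes iff the session's subject id and every scan's PatientID fully
#' match the configured regular expression (no partial matches; interior
#' whitespace or an empty id fails).
#'
#' @param session An `nqc_session`.
#' @param pattern Regular-expression string (PCRE).
#' @return A [qc_result()].
#' @export
id_matches_pattern <- function(session, pattern) {
  ok <- try(grepl(pattern, "x", perl = TRUE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("subject id pattern '%s' does not compile", pattern))
  }
  full <- sprintf("^(?:%s)$", pattern)
  ids <- c(subject = session$subject_id,
           vapply(session$scans, function(s) {
             scan_meta(s, "PatientID") %||% ""
           }, character(1)))
  bad <- ids[!grepl(full, ids, perl = TRUE)]
  qc_result(length(bad) == 0L,
            if (length(bad)) {
              purrr::imap(as.list(bad), function(v, k) {
                list(source = k, id = v, pattern = pattern)
              })
            } else list(sprintf("id '%s' matches '%s'", session$subject_id,
                                pattern)))
}

# SeriesDescription marks a T1-weighted scan when it contains the
# configured designation substring (case-insensitive).
is_t1_scan <- function(scan, t1_designation) {
  sd <- scan_meta(scan, "SeriesDescription")
  !is.null(sd) && grepl(t1_designation, sd, ignore.case = TRUE)
}

#' Usable T1-weighted image lookup
#'
#' Passes iff some MR session of the same subject contains a T1-weighted
#' scan (SeriesDescription matching the configured designation) whose
#' quality flag is `usable`. A usable T1 is the anatomical prerequisite of
#' the PET quantification pipelines.
#'
#' @param project An `nqc_project` (the lookup is project-scoped).
#' @param session The (typically PET) session whose subject is checked.
#' @param config A [qc_config()] (field `t1_designation`).
#' @return A [qc_result()]; on success the detail payload names the found
#'   scan.
#' @export
has_usable_t1 <- function(project, session, config = qc_config()) {
  if (is.null(project)) {
    return(qc_result(FALSE, list("no project context: cannot search for a usable T1")))
  }
  for (mr in subject_sessions(project, session$subject_id, "MR")) {
    for (scan in mr$scans) {
      if (is_t1_scan(scan, config$t1_designation) &&
          scan$quality_flag == "usable") {
        return(qc_result(TRUE, list(list(session = mr$session_id,
                                         scan = scan$scan_id,
                                         quality_flag = scan$quality_flag))))
      }
    }
  }
  qc_result(FALSE, list(sprintf(
    "no usable T1-weighted scan found for subject '%s'", session$subject_id)))
}

session_tracer <- function(session) {
  for (scan in session$scans) {
    val <- scan_meta(scan, "Radiopharmaceutical")
    if (!is.null(val)) return(norm_str(val))
  }
  NULL
}

session_has_nifti <- function(session) {
  any(vapply(session$scans, function(scan) {
    isTRUE(scan_has_nifti(scan)$has_passed)
  }, logical(1)))
}

#' Quantification-pipeline runnability check
#'
#' Assesses whether a PET session is suited for a quantification pipeline:
#' the Centiloid pipeline requires a flutemetamol (amyloid) session, the
#' FDG pipeline an FDG session; both additionally require a converted PET
#' NIfTI volume and a usable T1-weighted image for the subject (see
#' [has_usable_t1()]). A session whose tracer does not match the pipeline
#' (or is unknown) is out of the pipeline's scope and yields a pass with a
#' "not applicable" note, so a clean session is all-green.
#'
#' @param project An `nqc_project`.
#' @param session A PET `nqc_session`.
#' @param pipeline `"centiloid"` or `"fdg"`.
#' @param config A [qc_config()].
#' @return A [qc_result()]; the detail payload states which precondition
#'   failed.
#' @export
quantification_runnable <- function(project, session,
                                    pipeline = c("centiloid", "fdg"),
                                    config = qc_config()) {
  pipeline <- match.arg(pipeline)
  wanted <- c(centiloid = "FLUTEMETAMOL", fdg = "FDG")[[pipeline]]
  tracer <- session_tracer(session)
  if (is.null(tracer) || tracer != wanted) {
    return(qc_result(TRUE, list(sprintf(
      "not applicable: tracer %s does not target the %s pipeline",
      tracer %||% "unknown", pipeline))))
  }
  failed <- list()
  t1 <- has_usable_t1(project, session, config)
  if (!t1$has_passed) {
    failed[[length(failed) + 1L]] <- "precondition failed: no usable T1-weighted image"
  }
  if (!session_has_nifti(session)) {
    failed[[length(failed) + 1L]] <- "precondition failed: no readable PET NIfTI volume"
  }
  qc_result(length(failed) == 0L,
            if (length(failed)) failed else
              list(sprintf("%s pipeline runnable (tracer %s, usable T1 found)",
                           pipeline, tracer)))
}

#' NIfTI conversion check (scan level)
#'
#' Passes iff the scan's files include at least one readable NIfTI volume,
#' i.e. the DICOM series was converted. A truncated or corrupt file fails
#' with the read error in the detail payload.
#'
#' @param scan An `nqc_scan`.
#' @return A [qc_result()].
#' @export
scan_has_nifti <- function(scan) {
  nii <- grep("\\.nii(\\.gz)?$", scan$files, value = TRUE)
  if (!length(nii)) {
    return(qc_result(FALSE, list(sprintf("scan '%s': no NIfTI file present",
                                         scan$scan_id))))
  }
  for (f in nii) {
    # RNifti reports some corrupt files as a warning + NULL rather than an
    # error; both count as unreadable
    hdr <- tryCatch(RNifti::niftiHeader(file.path(scan$path, f)),
                    error = function(e) e, warning = function(w) w)
    if (!inherits(hdr, "condition") && !is.null(hdr)) {
      return(qc_result(TRUE, list(sprintf("scan '%s': readable NIfTI '%s'",
                                          scan$scan_id, f))))
    }
    err <- if (inherits(hdr, "condition")) conditionMessage(hdr) else
      "empty header"
  }
  qc_result(FALSE, list(sprintf("scan '%s': NIfTI unreadable: %s",
                                scan$scan_id, err)))
}
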