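#' Pipeline output manifest check
#'
#' Passes iff every expected entry (glob patterns allowed) matches at
#' least one file present in the resource. Unexpected extra files are
#' reported in the detail payload but do not fail the check — pipelines
#' add logs freely.
#'
#' @param resource An `nqc_resource`.
#' @param manifest Character vector of expected relative paths or glob
#'   patterns.
#' @return A [qc_result()]; failures list the missing patterns.
#' @export
has_correct_items <- function(resource, manifest) {
  stopifnot(length(manifest) > 0L)
  present <- resource$files$path
  matched <- logical(length(present))
  missing <- character(0)
  for (pat in manifest) {
    hit <- grepl(utils::glob2rx(pat), present)
    if (!any(hit)) missing <- c(missing, pat)
    matched <- matched | hit
  }
  data <- list()
  if (length(missing)) {
    data[[length(data) + 1L]] <- list(missing = as.list(missing))
  }
  unexpected <- setdiff(present[!matched], "provenance.json")
  if (length(unexpected)) {
    data[[length(data) + 1L]] <- list(unexpected = as.list(unexpected))
  }
  if (!length(data)) {
    data <- list(sprintf("all %d expected item(s) present in resource '%s'",
                         length(manifest), resource$name))
  }
  qc_result(length(missing) == 0L, data)
}

#' Pipeline software version check
#'
#' Passes iff the resource's provenance records exactly the expected
#' software version string. Absent provenance is a failure.
#'
#' @param resource An `nqc_resource`.
#' @param expected Expected version string (exact match).
#' @return A [qc_result()].
#' @export
has_correct_version <- function(resource, expected) {
  ver <- resource$provenance$software_version
  if (is.null(ver)) {
    return(qc_result(FALSE, list(sprintf(
      "resource '%s': no provenance record with a software version",
      resource$name))))
  }
  qc_result(identical(as.character(ver), as.character(expected)),
            list(list(resource = resource$name, found = ver,
                      expected = expected)))
}

#' Pipeline execution time check
#'
#' Passes iff the provenance timestamps show an elapsed wall time of at
#' most `max_seconds`. The elapsed time is recorded in the detail payload;
#' absent timestamps fail with a note.
#'
#' @param resource An `nqc_resource`.
#' @param max_seconds Threshold in seconds.
#' @return A [qc_result()].
#' @export
execution_time_within <- function(resource, max_seconds) {
  prov <- resource$provenance
  if (is.null(prov$started) || is.null(prov$finished)) {
    return(qc_result(FALSE, list(sprintf(
      "resource '%s': provenance lacks started/finished timestamps",
      resource$name))))
  }
  elapsed <- as.numeric(difftime(parse_time(prov$finished),
                                 parse_time(prov$started), units = "secs"))
  qc_result(elapsed <= max_seconds,
            list(list(resource = resource$name, elapsed_seconds = elapsed,
                      max_seconds = max_seconds)))
}

as_labelmap <- function(labelmap) {
  if (is.character(labelmap)) labelmap <- RNifti::readNifti(labelmap)
  labelmap
}

voxel_volume_mm3 <- function(labelmap) {
  if (inherits(labelmap, "niftiImage")) {
    pd <- RNifti::pixdim(labelmap)
    prod(pd[seq_len(min(3L, length(pd)))])
  } else {
    1
  }
}

#' Compute per-label volumes from a segmentation label map
#'
#' Each label's volume is its voxel count times the voxel volume taken
#' from the NIfTI header dimensions (anisotropic voxels supported; no
#' affine resampling). Label 0 is background and excluded.
#'
#' @param labelmap A NIfTI label map (`niftiImage`, array, or file path).
#'   Values must be integral.
#' @param labels Optional label subset to report (absent labels are
#'   reported with volume 0).
#' @return A tibble with columns `label` (character), `voxels` (integer)
#'   and `volume_mm3` (double).
#' @export
compute_label_volumes <- function(labelmap, labels = NULL) {
  labelmap <- as_labelmap(labelmap)
  vals <- as.vector(labelmap)
  if (any(vals != round(vals))) {
    abort("label map contains non-integer values")
  }
  vox <- voxel_volume_mm3(labelmap)
  counts <- table(vals[vals != 0])
  out <- tibble(label = names(counts),
                voxels = as.integer(counts),
                volume_mm3 = as.integer(counts) * vox)
  if (!is.null(labels)) {
    out <- tibble(label = as.character(labels)) |>
      dplyr::left_join(out, by = "label") |>
      dplyr::mutate(voxels = dplyr::coalesce(.data$voxels, 0L),
                    volume_mm3 = dplyr::coalesce(.data$volume_mm3, 0))
  }
  out
}

#' Segmentation label completeness check
#'
#' Passes iff every expected label appears in the label map with at least
#' one voxel (vacuously true for an empty expectation). The detail payload
#' lists absent labels.
#'
#' @param labelmap A NIfTI label map (`niftiImage`, array, or file path).
#' @param expected_labels Vector of expected integer labels.
#' @return A [qc_result()].
#' @export
has_all_subfields <- function(labelmap, expected_labels) {
  labelmap <- as_labelmap(labelmap)
  present <- unique(as.vector(labelmap))
  absent <- setdiff(as.numeric(expected_labels), present)
  qc_result(length(absent) == 0L,
            if (length(absent)) list(list(absent_labels = as.list(absent)))
            else list(sprintf("all %d expected label(s) present",
                              length(expected_labels))))
}

#' Volume safety-interval check
#'
#' Passes iff every region that has both a computed volume and a
#' configured interval lies inside it (inclusive). Regions without an
#' interval are ignored; regions keyed in the intervals map but absent
#' from the volume table are also ignored here — label *presence* is
#' [has_all_subfields()]'s job, keeping the two checks orthogonal.
#' Intervals with unit `"fraction"` are compared against
#' `volume / total_volume`.
#'
#' @param volumes A volume table as returned by [compute_label_volumes()]
#'   or [parse_aseg_stats()] (columns `label`, `volume_mm3`).
#' @param intervals Named list of [interval_spec()] keyed by label/region.
#' @param total_volume Total image volume in mm3; required when any
#'   interval has unit `"fraction"`.
#' @return A [qc_result()]; failures record (region, volume, interval).
#' @export
volumes_within_intervals <- function(volumes, intervals, total_volume = NULL) {
  bad <- list()
  for (region in names(intervals)) {
    iv <- intervals[[region]]
    stopifnot(inherits(iv, "qc_interval"))
    row <- volumes[volumes$label == region, ]
    if (nrow(row) == 0L) next
    value <- row$volume_mm3[1]
    if (identical(iv$unit, "fraction")) {
      if (is.null(total_volume)) {
        abort("total_volume required for fraction-unit intervals")
      }
      value <- value / total_volume
    }
    if (value < iv$lower || value > iv$upper) {
      bad[[length(bad) + 1L]] <- list(
        region = region, value = value,
        interval = sprintf("[%g, %g] %s", iv$lower, iv$upper, iv$unit))
    }
  }
  qc_result(length(bad) == 0L,
            if (length(bad)) bad else
              list(sprintf("%d region(s) within their safety intervals",
                           length(intervals))))
}

#' Parse a FreeSurfer aseg.stats table
#'
#' Reads the subcortical segmentation statistics format: comment header
#' lines beginning with `#` (including a `# ColHeaders` line naming the
#' columns) followed by a whitespace-delimited table. Only the
#' `StructName` and `Volume_mm3` columns are required.
#'
#' @param file Path to an `aseg.stats` file.
#' @return A tibble with columns `label` (structure name) and
#'   `volume_mm3`, one row per table row.
#' @export
parse_aseg_stats <- function(file) {
  lines <- readLines(file, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  ch <- grep("^# ColHeaders", header, value = TRUE)
  if (!length(ch)) abort(sprintf("'%s': no '# ColHeaders' line", file))
  cols <- strsplit(trimws(sub("^# ColHeaders", "", ch[1])), "\\s+")[[1]]
  for (needed in c("StructName", "Volume_mm3")) {
    if (!needed %in% cols) {
      abort(sprintf("'%s': missing column '%s'", file, needed))
    }
  }
  if (!length(body)) {
    return(tibble(label = character(0), volume_mm3 = numeric(0)))
  }
  tab <- utils::read.table(text = body, col.names = cols,
                           stringsAsFactors = FALSE)
  tibble(label = as.character(tab$StructName),
         volume_mm3 = as.numeric(tab$Volume_mm3))
}
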