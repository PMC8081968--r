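#' Aggregate FreeSurfer aseg.stats volumes over a project
#'
#' One row per session possessing a parseable `aseg.stats` under its
#' `FREESURFER6` resource; one column per structure name (taken verbatim
#' from `StructName`), the column union across sessions; cells are
#' `Volume_mm3`, missing where a session lacks the structure. Sessions
#' without the resource are skipped with a note; parse failures are
#' collected, never fatal.
#'
#' @param project An `nqc_project`.
#' @param resource_name Resource holding the stats (default
#'   `"FREESURFER6"`).
#' @param stats_file Relative path of the stats table inside the resource.
#' @return A tibble with columns `session_id`, `subject_id` and one column
#'   per structure; attribute `"notes"` lists skipped sessions.
#' @export
aggregate_aseg <- function(project, resource_name = "FREESURFER6",
                           stats_file = "stats/aseg.stats") {
  notes <- character(0)
  rows <- list()
  for (sess in project$sessions) {
    res <- sess$resources[[resource_name]]
    if (is.null(res)) {
      notes <- c(notes, sprintf("session '%s': no %s resource",
                                sess$session_id, resource_name))
      next
    }
    f <- file.path(res$path, stats_file)
    if (!file.exists(f)) {
      notes <- c(notes, sprintf("session '%s': no %s", sess$session_id,
                                stats_file))
      next
    }
    vols <- tryCatch(parse_aseg_stats(f), error = function(e) {
      notes <<- c(notes, sprintf("session '%s': parse failure: %s",
                                 sess$session_id, conditionMessage(e)))
      NULL
    })
    if (is.null(vols)) next
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble(session_id = sess$session_id,
                              subject_id = sess$subject_id),
                       tidyr::pivot_wider(vols, names_from = "label",
                                          values_from = "volume_mm3"))
  }
  out <- if (length(rows)) {
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$session_id)
  } else {
    tibble(session_id = character(0), subject_id = character(0))
  }
  attr(out, "notes") <- notes
  out
}

validator_test_order <- function(validator_name) {
  v <- qc_registry()[[validator_name]]
  if (is.null(v)) return(NULL)
  vapply(v$tests, `[[`, "", "id")
}

#' Aggregate persisted test outcomes over a project
#'
#' Builds a session-by-test table from the validation report JSONs
#' persisted by [run_validator()]. Column order follows the validator's
#' declaration order; cells are the reports' `has_passed` booleans.
#' Sessions lacking a report get a row of `NA` cells plus a note.
#'
#' @param project An `nqc_project`.
#' @param validator_name Validator (and report resource) name.
#' @return A tibble with columns `session_id`, `subject_id`, then one
#'   logical column per test id; attribute `"notes"` lists sessions
#'   without a report.
#' @export
aggregate_tests <- function(project, validator_name) {
  order_ids <- validator_test_order(validator_name)
  notes <- character(0)
  rows <- list()
  for (sess in project$sessions) {
    f <- file.path(sess$path, "resources", validator_name, "report.json")
    base <- tibble(session_id = sess$session_id, subject_id = sess$subject_id)
    if (!file.exists(f)) {
      notes <- c(notes, sprintf("session '%s': no %s report",
                                sess$session_id, validator_name))
      rows[[length(rows) + 1L]] <- base
      next
    }
    report <- report_from_json(f)
    ids <- vapply(report$results, `[[`, "", "id")
    vals <- vapply(report$results, `[[`, logical(1), "has_passed")
    if (is.null(order_ids)) order_ids <- ids
    cells <- stats::setNames(as.list(vals[match(order_ids, ids)]), order_ids)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(base, tibble(!!!cells))
  }
  out <- if (length(rows)) {
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$session_id)
  } else {
    tibble(session_id = character(0), subject_id = character(0))
  }
  if (!is.null(order_ids)) {
    for (id in setdiff(order_ids, names(out))) out[[id]] <- NA
    out <- dplyr::relocate(out, dplyr::all_of(order_ids),
                           .after = "subject_id")
  }
  attr(out, "notes") <- notes
  out
}

#' Copy a named resource out of every session
#'
#' Copies (never moves) each session's `resources/<resource_name>` tree
#' into `dest_dir/<subject>_<session>/`.
#'
#' @param project An `nqc_project`.
#' @param resource_name Resource to collect (e.g. `"FREESURFER6"`).
#' @param dest_dir Destination directory (created).
#' @return A tibble with columns `session_id`, `subject_id`, `dest`; a
#'   warning is raised when no session carries the resource.
#' @export
collect_files <- function(project, resource_name, dest_dir) {
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sess in project$sessions) {
    res <- sess$resources[[resource_name]]
    if (is.null(res)) next
    dest <- file.path(dest_dir, paste0(sess$subject_id, "_", sess$session_id))
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    for (rel in res$files$path) {
      target <- file.path(dest, rel)
      dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
      file.copy(file.path(res$path, rel), target, overwrite = TRUE,
                copy.date = TRUE)
    }
    rows[[length(rows) + 1L]] <- tibble(session_id = sess$session_id,
                                        subject_id = sess$subject_id,
                                        dest = dest)
  }
  if (!length(rows)) {
    warn(sprintf("no session carries a '%s' resource", resource_name))
    return(tibble(session_id = character(0), subject_id = character(0),
                  dest = character(0)))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$session_id)
}

#' Collect report snapshots into one folder for visual review
#'
#' Extracts every snapshot image referenced by a validator's persisted
#' reports, copies them into one flat folder under unique names
#' (`<subject>_<session>_<file>`), and writes a `manifest.csv` mapping
#' each snapshot to its session and the per-test outcomes of its report —
#' the input expected by [load_gallery()].
#'
#' @param project An `nqc_project`.
#' @param validator_name Validator whose reports are scanned.
#' @param dest_dir Destination folder (created).
#' @return The manifest tibble (`snapshot_id`, `session_id`,
#'   `subject_id`, one logical column per test), invisibly written to
#'   `dest_dir/manifest.csv`.
#' @export
collect_snapshots <- function(project, validator_name, dest_dir) {
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  outcomes <- aggregate_tests(project, validator_name)
  rows <- list()
  for (sess in project$sessions) {
    rdir <- file.path(sess$path, "resources", validator_name)
    if (!file.exists(file.path(rdir, "report.json"))) next
    images <- list.files(rdir, pattern = "\\.(png|gif)$")
    for (img in images) {
      snap_id <- paste0(sess$subject_id, "_", sess$session_id, "_", img)
      file.copy(file.path(rdir, img), file.path(dest_dir, snap_id),
                overwrite = TRUE)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(snapshot_id = snap_id),
                         outcomes[outcomes$session_id == sess$session_id, ])
    }
  }
  manifest <- if (length(rows)) {
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$snapshot_id)
  } else {
    tibble(snapshot_id = character(0), session_id = character(0),
           subject_id = character(0))
  }
  utils::write.csv(manifest, file.path(dest_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
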