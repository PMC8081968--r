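#' Load a snapshot gallery for visual review
#'
#' Joins the snapshot images found in a folder to the per-test outcomes of
#' the collect manifest (see [collect_snapshots()]). Snapshots absent from
#' the manifest carry empty (NA) outcomes. Entry order is deterministic
#' (lexicographic by snapshot id).
#'
#' @param snapshot_dir Folder of snapshot images.
#' @param manifest Manifest tibble or path to a `manifest.csv`.
#' @return A tibble of class `qc_gallery` with columns `snapshot_id`,
#'   `path`, `session_id`, `subject_id` and one column per test outcome.
#' @export
load_gallery <- function(snapshot_dir, manifest = NULL) {
  if (is.null(manifest)) {
    mf <- file.path(snapshot_dir, "manifest.csv")
    manifest <- if (file.exists(mf)) mf else
      tibble(snapshot_id = character(0), session_id = character(0),
             subject_id = character(0))
  }
  if (is.character(manifest)) {
    manifest <- as_tibble(utils::read.csv(manifest, stringsAsFactors = FALSE))
  }
  images <- sort(list.files(snapshot_dir, pattern = "\\.(png|gif)$"))
  gallery <- tibble(snapshot_id = images,
                    path = file.path(snapshot_dir, images)) |>
    dplyr::left_join(manifest, by = "snapshot_id")
  class(gallery) <- c("qc_gallery", class(gallery))
  gallery
}

REVIEW_COLUMNS <- c("snapshot_id", "rater", "score", "comment", "timestamp")

#' Record a rater's score for a snapshot
#'
#' Appends one review record (score + free-text comment) to the tabular
#' score store. The store is an append-only TSV log guarded by a per-append
#' file lock, so concurrent raters never lose records; edits are new rows
#' and the "current" view is the latest record per (snapshot, rater) —
#' see [current_reviews()].
#'
#' @param store Path to the TSV score store (created on first use).
#' @param snapshot_id Snapshot identifier.
#' @param rater Rater name.
#' @param score Integer score on the configured scale.
#' @param comment Free-text comment.
#' @param scale Allowed scores (default `0:2`: fail / doubtful / pass).
#' @param time Record timestamp.
#' @return The appended record as a one-row tibble, invisibly.
#' @export
upsert_review <- function(store, snapshot_id, rater, score, comment = "",
                          scale = 0:2, time = Sys.time()) {
  if (!is.numeric(score) || length(score) != 1L || !score %in% scale) {
    abort(sprintf("score %s outside the configured scale {%s}",
                  as.character(score)[1], paste(scale, collapse = ", ")))
  }
  rec <- tibble(snapshot_id = snapshot_id, rater = rater,
                score = as.integer(score),
                comment = gsub("[\t\n]", " ", comment),
                timestamp = qc_timestamp(time))
  with_file_lock(store, {
    new <- !file.exists(store)
    utils::write.table(rec, store, sep = "\t", row.names = FALSE,
                       col.names = new, quote = FALSE, append = !new)
  })
  invisible(rec)
}

#' Read the review store
#'
#' `read_reviews()` returns the full append-only history;
#' `current_reviews()` the current view — the latest record per
#' (snapshot, rater), a pure function of the history.
#'
#' @param store Path to the TSV score store.
#' @return A tibble with columns `snapshot_id`, `rater`, `score`,
#'   `comment`, `timestamp`.
#' @export
read_reviews <- function(store) {
  if (!file.exists(store)) {
    return(tibble(snapshot_id = character(0), rater = character(0),
                  score = integer(0), comment = character(0),
                  timestamp = character(0)))
  }
  as_tibble(utils::read.table(store, sep = "\t", header = TRUE,
                              colClasses = c("character", "character",
                                             "integer", "character",
                                             "character"),
                              quote = "", comment.char = ""))
}

#' @rdname read_reviews
#' @export
current_reviews <- function(store) {
  read_reviews(store) |>
    dplyr::mutate(.order = dplyr::row_number()) |>
    dplyr::group_by(.data$snapshot_id, .data$rater) |>
    dplyr::slice_max(.data$.order, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$snapshot_id, .data$rater) |>
    dplyr::select(-".order")
}

#' Jump to the next snapshot failing a chosen checkpoint
#'
#' Navigation helper for assisted review: given the gallery and a selected
#' test, returns the smallest index after the current one whose outcome
#' for that test is a failure, wrapping around to the first failed entry.
#' When no entry fails the test, the current index is returned with a
#' notice.
#'
#' @param gallery A `qc_gallery` (see [load_gallery()]).
#' @param test_id Name of the outcome column to navigate by.
#' @param current_index Current 1-based gallery index.
#' @return The next failed index (integer).
#' @export
next_failed <- function(gallery, test_id, current_index) {
  if (!test_id %in% names(gallery)) {
    abort(sprintf("unknown test '%s' in gallery manifest", test_id))
  }
  failed <- which(!is.na(gallery[[test_id]]) & gallery[[test_id]] == FALSE)
  if (!length(failed)) {
    inform(sprintf("no snapshot fails '%s'", test_id))
    return(as.integer(current_index))
  }
  after <- failed[failed > current_index]
  as.integer(if (length(after)) after[1] else failed[1])
}

#' Export the current review scores as a spreadsheet
#'
#' Writes the current view (latest record per snapshot and rater) as a
#' CSV spreadsheet; re-export is idempotent.
#'
#' @param store Path to the TSV score store.
#' @param dest Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
export_reviews <- function(store, dest) {
  cur <- current_reviews(store)
  utils::write.csv(cur, dest, row.names = FALSE)
  invisible(cur)
}

#' Render a static review gallery page
#'
#' Generates a single self-contained HTML page over the snapshot gallery:
#' each entry shows the snapshot, red/green badges for its checkpoint
#' outcomes, the current scores, and a link to the session directory. All
#' review logic lives in the store/navigation operations, so this page is
#' a minimal, replaceable surface.
#'
#' @param gallery A `qc_gallery`.
#' @param store Optional path to the score store (current scores shown).
#' @param dest Output HTML path.
#' @return `dest`, invisibly.
#' @export
render_gallery_html <- function(gallery, store = NULL, dest) {
  scores <- if (!is.null(store)) current_reviews(store) else NULL
  test_cols <- setdiff(names(gallery),
                       c("snapshot_id", "path", "session_id", "subject_id"))
  blocks <- vapply(seq_len(nrow(gallery)), function(i) {
    row <- gallery[i, ]
    badges <- paste(vapply(test_cols, function(tc) {
      val <- row[[tc]]
      col <- if (is.na(val)) "#999" else if (isTRUE(val)) "#2a2" else "#c22"
      sprintf("<span style=\"background:%s;color:#fff;padding:2px 6px;margin:2px;border-radius:3px\">%s</span>",
              col, html_escape(tc))
    }, ""), collapse = "")
    score_txt <- ""
    if (!is.null(scores)) {
      sc <- scores[scores$snapshot_id == row$snapshot_id, ]
      if (nrow(sc)) {
        score_txt <- paste(sprintf("%s: %d (%s)", sc$rater, sc$score,
                                   html_escape(sc$comment)), collapse = "; ")
      }
    }
    sprintf(paste0(
      "<div class=\"snap\"><h3>%s</h3><img src=\"%s\" style=\"max-width:100%%\"/>",
      "<div>%s</div><div>session: %s</div><div>scores: %s</div></div>"),
      html_escape(row$snapshot_id), html_escape(basename(row$path)), badges,
      html_escape(row$session_id %||% ""), score_txt)
  }, "")
  html <- paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
                 "<title>snapshot review</title></head><body>\n",
                 paste(blocks, collapse = "\n"), "\n</body></html>\n")
  writeLines(html, dest)
  invisible(dest)
}
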