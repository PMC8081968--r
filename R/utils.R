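#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic ISO-8601 UTC timestamp; injectable for reproducible reports.
qc_timestamp <- function(time = Sys.time()) {
  format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# Atomic-ish cross-process lock: dir.create() is atomic on POSIX filesystems.
with_file_lock <- function(path, expr, timeout = 10) {
  lockdir <- paste0(path, ".lock")
  t0 <- Sys.time()
  repeat {
    if (suppressWarnings(dir.create(lockdir, showWarnings = FALSE))) break
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > timeout) {
      abort(sprintf("could not acquire lock on '%s'", path))
    }
    Sys.sleep(0.05)
  }
  on.exit(unlink(lockdir, recursive = TRUE), add = TRUE)
  force(expr)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Minimal Markdown renderer covering the subset the report writer emits:
# ATX headings, unordered lists, bold/code spans, images, paragraphs.
markdown_to_html <- function(md, title = "report") {
  lines <- strsplit(md, "\n", fixed = TRUE)[[1]]
  out <- character(0)
  in_list <- FALSE
  close_list <- function() {
    if (in_list) {
      out[[length(out) + 1L]] <<- "</ul>"
      in_list <<- FALSE
    }
  }
  spans <- function(x) {
    x <- html_escape(x)
    x <- gsub("!\\[([^]]*)\\]\\(([^)]+)\\)", "<img src=\"\\2\" alt=\"\\1\"/>", x)
    x <- gsub("\\*\\*([^*]+)\\*\\*", "<strong>\\1</strong>", x)
    gsub("`([^`]+)`", "<code>\\1</code>", x)
  }
  for (ln in lines) {
    if (grepl("^#{1,6} ", ln)) {
      close_list()
      lvl <- nchar(sub("^(#+).*$", "\\1", ln))
      out[[length(out) + 1L]] <-
        sprintf("<h%d>%s</h%d>", lvl, spans(sub("^#+ +", "", ln)), lvl)
    } else if (grepl("^[-*] ", ln)) {
      if (!in_list) {
        out[[length(out) + 1L]] <- "<ul>"
        in_list <- TRUE
      }
      out[[length(out) + 1L]] <- sprintf("<li>%s</li>", spans(sub("^[-*] +", "", ln)))
    } else if (nzchar(trimws(ln))) {
      close_list()
      out[[length(out) + 1L]] <- sprintf("<p>%s</p>", spans(ln))
    } else {
      close_list()
    }
  }
  close_list()
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>",
         html_escape(title), "</title></head>\n<body>\n",
         paste(out, collapse = "\n"), "\n</body></html>\n")
}
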