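#' One checkpoint outcome
#'
#' Every checkpoint yields a binary outcome (`has_passed`) plus a free-form
#' detail payload (`data`), a list of strings or small named records used
#' for logging and report generation.
#'
#' @param has_passed Logical scalar.
#' @param data List of detail items (coerced to a list; may be empty).
#' @return An object of class `qc_result`.
#' @export
qc_result <- function(has_passed, data = list()) {
  stopifnot(is.logical(has_passed), length(has_passed) == 1L, !is.na(has_passed))
  if (!is.list(data)) data <- as.list(data)
  structure(list(has_passed = has_passed, data = data), class = "qc_result")
}

#' Define one checkpoint (a Test)
#'
#' A Test is one self-documented checkpoint run against an imaging session
#' (or each of its scans). Its docstring is the human-readable
#' specification of what it verifies and is copied verbatim into every
#' report section. Each Test also names a passing and a failing fixture
#' session, used by [self_check()] to continuously verify the Test itself.
#'
#' @param id Test identifier, unique within a validator.
#' @param docstring Non-empty human-readable specification text.
#' @param level `"session"` (run once per session) or `"scan"` (run on
#'   every scan; the overall outcome is the conjunction).
#' @param run For session-level tests `function(session, ctx)`, for
#'   scan-level tests `function(scan, ctx)`, returning a [qc_result()].
#'   `ctx` carries `session`, `project`, `config` and `out_dir` (the report
#'   resource directory, where snapshot tests drop their images).
#' @param passing,failing Fixture references: the session id of a fixture
#'   session on which the test must pass / fail (see [make_project()]).
#' @param on_fail_flag Optional quality flag (`"questionable"` or
#'   `"unusable"`) applied to implicated scans when the test fails.
#' @return An object of class `qc_test`.
#' @export
qc_test <- function(id, docstring, level = c("session", "scan"), run,
                    passing, failing, on_fail_flag = NULL) {
  level <- match.arg(level)
  stopifnot(nzchar(id), is.character(docstring), nzchar(trimws(docstring)),
            is.function(run))
  if (identical(passing, failing)) {
    abort(sprintf("test '%s': passing and failing fixtures must differ", id))
  }
  if (!is.null(on_fail_flag)) {
    on_fail_flag <- match.arg(on_fail_flag, c("questionable", "unusable"))
  }
  structure(
    list(id = id, docstring = docstring, level = level, run = run,
         passing = passing, failing = failing, on_fail_flag = on_fail_flag),
    class = "qc_test"
  )
}

#' Define a validator: an ordered set of Tests
#'
#' @param name Validator name (also used as the report resource name).
#' @param tests List of [qc_test()] objects; order is the report order.
#' @return An object of class `qc_validator`.
#' @export
qc_validator <- function(name, tests) {
  stopifnot(nzchar(name), is.list(tests))
  ids <- vapply(tests, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    abort(sprintf("validator '%s': duplicate test ids: %s", name,
                  paste(ids[duplicated(ids)], collapse = ", ")))
  }
  structure(list(name = name, tests = tests), class = "qc_validator")
}

new_ctx <- function(session, project = NULL, config = qc_config(),
                    out_dir = NULL) {
  list(session = session, project = project, config = config, out_dir = out_dir)
}

#' Run one Test against a session
#'
#' Session-level tests run once. Scan-level tests run on every scan of the
#' session; the overall outcome is the conjunction and the per-scan
#' outcomes are recorded in `data`. An exception raised inside a test is
#' converted into a failed result carrying the error message — it never
#' aborts the surrounding validator. On failure, a test's `on_fail_flag`
#' downgrades the implicated scans via [set_quality_flag()].
#'
#' @param test A [qc_test()].
#' @param session An `nqc_session`.
#' @param project Optional `nqc_project` (required by project-scope tests
#'   such as the usable-T1 lookup).
#' @param config A [qc_config()].
#' @param out_dir Directory where report-attached artifacts (snapshots) are
#'   written; defaults to a temporary directory.
#' @return A [qc_result()].
#' @export
run_test <- function(test, session, project = NULL, config = qc_config(),
                     out_dir = NULL) {
  stopifnot(inherits(test, "qc_test"), inherits(session, "nqc_session"))
  ctx <- new_ctx(session, project, config, out_dir %||% tempdir())
  safely_run <- function(f, target) {
    tryCatch({
      res <- f(target, ctx)
      stopifnot(inherits(res, "qc_result"))
      res
    }, error = function(e) {
      qc_result(FALSE, list(sprintf("test error: %s", conditionMessage(e))))
    })
  }
  if (test$level == "session") {
    res <- safely_run(test$run, session)
    failing_scans <- names(session$scans)
  } else {
    per_scan <- lapply(session$scans, function(scan) safely_run(test$run, scan))
    ok <- vapply(per_scan, `[[`, logical(1), "has_passed")
    res <- qc_result(all(ok) || length(ok) == 0L, unname(purrr::imap(
      per_scan,
      function(r, id) list(scan = id, has_passed = r$has_passed, data = r$data))))
    failing_scans <- names(session$scans)[!ok]
  }
  if (!res$has_passed && !is.null(test$on_fail_flag)) {
    for (sid in failing_scans) {
      session$scans[[sid]] <- set_quality_flag(session$scans[[sid]],
                                               test$on_fail_flag)
    }
  }
  res
}

package_sha <- function() {
  desc <- utils::packageDescription("neuroqc")
  desc$RemoteSha %||% desc$GitSha %||% "unknown"
}

#' Run a validator over a session and produce a validation report
#'
#' All tests run sequentially in their declared order; failures never
#' short-circuit the sequence, so every report is a complete checklist.
#' The report carries provenance (validator name, code SHA when the
#' installed package records one, timestamp) and is persisted as a resource
#' of the session (JSON + Markdown + HTML) under
#' `resources/<validator name>/`.
#'
#' @param validator A [qc_validator()].
#' @param session An `nqc_session`.
#' @param project Optional `nqc_project` for project-scope tests.
#' @param config A [qc_config()].
#' @param persist Write the report into the session's resources (default
#'   `TRUE`).
#' @param time Report timestamp (injectable for deterministic output).
#' @return An object of class `qc_report`; see [tidy.qc_report()] and
#'   [glance.qc_report()] for tabular views.
#' @export
run_validator <- function(validator, session, project = NULL,
                          config = qc_config(), persist = TRUE,
                          time = Sys.time()) {
  stopifnot(inherits(validator, "qc_validator"))
  out_dir <- file.path(session$path, "resources", validator$name)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- lapply(validator$tests, function(test) {
    res <- run_test(test, session, project, config,
                    out_dir = if (persist) out_dir else NULL)
    list(id = test$id, docstring = test$docstring,
         has_passed = res$has_passed, data = res$data)
  })
  passed <- sum(vapply(results, `[[`, logical(1), "has_passed"))
  report <- structure(
    list(validator = validator$name, session_id = session$session_id,
         subject_id = session$subject_id, generated = qc_timestamp(time),
         code_sha = package_sha(), results = results,
         summary = list(passed = passed, failed = length(results) - passed)),
    class = "qc_report"
  )
  if (persist) {
    writeLines(report_to_json(report), file.path(out_dir, "report.json"))
    md <- report_to_markdown(report)
    writeLines(md, file.path(out_dir, "report.md"))
    writeLines(markdown_to_html(md, title = sprintf("%s %s", validator$name,
                                                    session$session_id)),
               file.path(out_dir, "report.html"))
  }
  report
}

#' Render a validation report as Markdown
#'
#' One section per test, in validator order. Each section contains the
#' test's docstring verbatim, the pass/fail outcome and a rendering of the
#' detail payload; detail items that are image paths are embedded as
#' Markdown images by relative path. The header carries the validator name,
#' session, subject, timestamp and code SHA.
#'
#' @param report A `qc_report`.
#' @return A single Markdown string.
#' @export
report_to_markdown <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  render_item <- function(item) {
    if (is.character(item) && length(item) == 1L &&
        grepl("\\.(png|gif|jpe?g)$", item, ignore.case = TRUE)) {
      return(sprintf("![snapshot](%s)", item))
    }
    if (is.list(item) || !is.null(names(item))) {
      return(paste(vapply(seq_along(item), function(i) {
        key <- names(item)[i] %||% ""
        val <- item[[i]]
        val <- if (is.list(val)) jsonlite::toJSON(val, auto_unbox = TRUE) else
          paste(as.character(val), collapse = ", ")
        if (nzchar(key)) sprintf("%s: %s", key, val) else val
      }, ""), collapse = "; "))
    }
    paste(as.character(item), collapse = ", ")
  }
  lines <- c(
    sprintf("# %s — validation report", report$validator),
    "",
    sprintf("- **Session**: %s", report$session_id),
    sprintf("- **Subject**: %s", report$subject_id),
    sprintf("- **Generated**: %s", report$generated),
    sprintf("- **Code SHA**: %s", report$code_sha),
    sprintf("- **Summary**: %d passed, %d failed",
            report$summary$passed, report$summary$failed),
    ""
  )
  for (i in seq_along(report$results)) {
    r <- report$results[[i]]
    lines <- c(lines,
               sprintf("## %d. %s — %s", i, r$id,
                       if (r$has_passed) "PASSED" else "FAILED"),
               "", r$docstring, "")
    for (item in r$data) {
      lines <- c(lines, sprintf("- %s", render_item(item)))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Serialize / deserialize validation reports as JSON
#'
#' The JSON schema is normative:
#' `{validator, session_id, subject_id, generated, code_sha,
#'   tests:[{id, docstring, has_passed, data}], summary:{passed, failed}}`.
#' `report_from_json()` validates the schema and errors naming the first
#' missing field; the round trip is the identity on all fields.
#'
#' @param report A `qc_report`.
#' @return `report_to_json()`: a JSON string. `report_from_json()`: a
#'   `qc_report`.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  payload <- list(
    validator = report$validator, session_id = report$session_id,
    subject_id = report$subject_id, generated = report$generated,
    code_sha = report$code_sha,
    tests = lapply(report$results, function(r) {
      list(id = r$id, docstring = r$docstring, has_passed = r$has_passed,
           data = r$data)
    }),
    summary = report$summary
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

#' @param json A JSON string, or a path to a JSON report file.
#' @rdname report_to_json
#' @export
report_from_json <- function(json) {
  obj <- if (length(json) == 1L && file.exists(json)) {
    read_json_file(json)
  } else {
    jsonlite::fromJSON(paste(json, collapse = "\n"), simplifyVector = FALSE)
  }
  for (field in c("validator", "session_id", "subject_id", "generated",
                  "code_sha", "tests", "summary")) {
    if (is.null(obj[[field]])) {
      abort(sprintf("report JSON lacks required field '%s'", field))
    }
  }
  results <- lapply(obj$tests, function(t) {
    for (field in c("id", "docstring", "has_passed")) {
      if (is.null(t[[field]])) {
        abort(sprintf("report JSON test entry lacks required field '%s'", field))
      }
    }
    list(id = t$id, docstring = t$docstring, has_passed = t$has_passed,
         data = t$data %||% list())
  })
  for (field in c("passed", "failed")) {
    if (is.null(obj$summary[[field]])) {
      abort(sprintf("report JSON summary lacks required field '%s'", field))
    }
  }
  structure(
    list(validator = obj$validator, session_id = obj$session_id,
         subject_id = obj$subject_id, generated = obj$generated,
         code_sha = obj$code_sha, results = results,
         summary = list(passed = obj$summary$passed,
                        failed = obj$summary$failed)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<%s report for session %s: %d passed, %d failed>\n",
              x$validator, x$session_id, x$summary$passed, x$summary$failed))
  invisible(x)
}

#' Self-check every shipped Test against its fixtures
#'
#' The continuous-integration core of the framework: every Test declares a
#' passing and a failing fixture session, and `self_check()` re-executes
#' each Test against both. On a correct build every row reads
#' `(passed_on_passing = TRUE, failed_on_failing = TRUE)`. Because all
#' Tests share one template, this harness needs no per-test updates as the
#' registry grows.
#'
#' @param validators List of [qc_validator()] objects (default: the shipped
#'   registry, [qc_registry()]).
#' @param project An `nqc_project` containing the fixture sessions (e.g.
#'   built with [make_selfcheck_project()]); fixture references are session
#'   ids within it.
#' @param config A [qc_config()].
#' @return A tibble with columns `validator`, `test_id`,
#'   `passed_on_passing`, `failed_on_failing`, `ok`, `note`. Unresolvable
#'   fixtures are flagged in `note` with `ok = FALSE`.
#' @export
self_check <- function(validators = qc_registry(), project,
                       config = qc_config()) {
  stopifnot(inherits(project, "nqc_project"))
  rows <- purrr::map_dfr(validators, function(v) {
    purrr::map_dfr(v$tests, function(test) {
      resolve <- function(ref) {
        sess <- project$sessions[[ref]]
        if (is.null(sess)) return(NULL)
        sess
      }
      note <- character(0)
      outcome <- function(ref, want_pass) {
        sess <- resolve(ref)
        if (is.null(sess)) {
          note <<- c(note, sprintf("unresolvable fixture '%s'", ref))
          return(NA)
        }
        res <- run_test(test, sess, project, config)
        if (want_pass) res$has_passed else !res$has_passed
      }
      pp <- outcome(test$passing, TRUE)
      ff <- outcome(test$failing, FALSE)
      tibble(validator = v$name, test_id = test$id,
             passed_on_passing = pp, failed_on_failing = ff,
             ok = isTRUE(pp) && isTRUE(ff),
             note = paste(note, collapse = "; "))
    })
  })
  class(rows) <- c("qc_selfcheck", class(rows))
  rows
}
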