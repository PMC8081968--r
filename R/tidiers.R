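#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a validation report into one row per test
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A tibble with columns `test_id`, `has_passed`, `n_details`,
#'   `docstring`, in report order.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    test_id = vapply(x$results, `[[`, "", "id"),
    has_passed = vapply(x$results, `[[`, logical(1), "has_passed"),
    n_details = vapply(x$results, function(r) length(r$data), integer(1)),
    docstring = vapply(x$results, `[[`, "", "docstring")
  )
}

#' One-row summary of a validation report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A one-row tibble: `validator`, `session_id`, `subject_id`,
#'   `generated`, `code_sha`, `passed`, `failed`.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(validator = x$validator, session_id = x$session_id,
         subject_id = x$subject_id, generated = x$generated,
         code_sha = x$code_sha, passed = x$summary$passed,
         failed = x$summary$failed)
}

#' Plot a validation report as a pass/fail checklist
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  df <- tidy(object)
  df$test_id <- factor(df$test_id, levels = rev(df$test_id))
  ggplot2::ggplot(df, ggplot2::aes(x = 1, y = .data$test_id,
                                   fill = .data$has_passed)) +
    ggplot2::geom_tile(color = "white", linewidth = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2a9d2a",
                                          `FALSE` = "#cc2222"),
                               name = "passed") +
    ggplot2::labs(title = sprintf("%s — %s", object$validator,
                                  object$session_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a self-check table
#'
#' @param object A `qc_selfcheck` tibble (see [self_check()]).
#' @param ... Unused.
#' @return A ggplot object with one tile per (validator, test).
#' @method autoplot qc_selfcheck
#' @export
autoplot.qc_selfcheck <- function(object, ...) {
  df <- tidyr::pivot_longer(object,
                            c("passed_on_passing", "failed_on_failing"),
                            names_to = "fixture", values_to = "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fixture, y = .data$test_id,
                                   fill = .data$ok)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.5) +
    ggplot2::facet_grid(.data$validator ~ ., scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2a9d2a",
                                          `FALSE` = "#cc2222"),
                               na.value = "#999999", name = "ok") +
    ggplot2::labs(x = NULL, y = NULL, title = "Self-check by fixture") +
    ggplot2::theme_minimal()
}
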