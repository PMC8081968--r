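fake_gallery <- function(outcomes) {
  g <- tibble::tibble(
    snapshot_id = sprintf("snap%03d.png", seq_along(outcomes)),
    path = sprintf("/dev/null/snap%03d.png", seq_along(outcomes)),
    session_id = sprintf("S%03d", seq_along(outcomes)),
    subject_id = "X",
    SomeTest = outcomes)
  class(g) <- c("qc_gallery", class(g))
  g
}

test_that("galleries join snapshots to manifest outcomes", {
  dir <- withr::local_tempdir()
  for (i in 1:10) {
    png::writePNG(matrix(i / 10, 4, 4), file.path(dir, sprintf("s%02d.png", i)))
  }
  manifest <- tibble::tibble(snapshot_id = sprintf("s%02d.png", 1:8),
                             session_id = sprintf("S%02d", 1:8),
                             subject_id = "A",
                             T1 = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                                    TRUE, TRUE))
  g <- load_gallery(dir, manifest)
  expect_equal(nrow(g), 10)
  expect_equal(g$snapshot_id, sort(g$snapshot_id))
  expect_equal(g$T1[g$snapshot_id == "s02.png"], FALSE)
  # snapshots absent from the manifest carry empty outcomes
  expect_true(is.na(g$T1[g$snapshot_id == "s09.png"]))
  expect_equal(nrow(load_gallery(withr::local_tempdir())), 0)
})

test_that("the score store is append-only with a latest-wins current view", {
  store <- file.path(withr::local_tempdir(), "scores.tsv")
  upsert_review(store, "a.png", "alice", 1, "hmm",
                time = as.POSIXct("2024-01-01 10:00:00", tz = "UTC"))
  first_bytes <- readBin(store, "raw", file.size(store))
  upsert_review(store, "a.png", "alice", 2, "fine on second look",
                time = as.POSIXct("2024-01-01 11:00:00", tz = "UTC"))
  # earlier bytes untouched: strictly appended
  expect_identical(readBin(store, "raw", length(first_bytes)), first_bytes)
  upsert_review(store, "a.png", "bob", 0,
                time = as.POSIXct("2024-01-01 12:00:00", tz = "UTC"))
  history <- read_reviews(store)
  expect_equal(nrow(history), 3)
  cur <- current_reviews(store)
  expect_equal(nrow(cur), 2)
  expect_equal(cur$score[cur$rater == "alice"], 2)
  expect_equal(cur$score[cur$rater == "bob"], 0)
  expect_error(upsert_review(store, "a.png", "alice", 7), "outside")
  expect_error(upsert_review(store, "a.png", "alice", -1), "outside")
  expect_equal(nrow(read_reviews(store)), 3)
})

test_that("next_failed matches a linear-scan oracle and wraps", {
  g <- fake_gallery(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(next_failed(g, "SomeTest", 2), 7)
  expect_equal(next_failed(g, "SomeTest", 7), 2)  # wrap to first failed
  all_pass <- fake_gallery(rep(TRUE, 4))
  expect_message(idx <- next_failed(all_pass, "SomeTest", 3), "no snapshot")
  expect_equal(idx, 3)
  expect_error(next_failed(g, "NotATest", 1), "unknown test")

  oracle <- function(fails, cur) {
    n <- length(fails)
    for (step in 1:n) {
      cand <- (cur + step - 1) %% n + 1
      if (cand > cur && fails[cand]) return(cand)
    }
    for (cand in seq_len(n)) if (fails[cand]) return(cand)
    cur
  }
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    outcomes <- sample(c(TRUE, FALSE), n, replace = TRUE)
    gal <- fake_gallery(outcomes)
    cur <- sample(n, 1)
    expect_equal(suppressMessages(next_failed(gal, "SomeTest", cur)),
                 oracle(outcomes == FALSE, cur),
                 info = sprintf("n=%d cur=%d", n, cur))
  }
})

test_that("review export writes the current view and is idempotent", {
  store <- file.path(withr::local_tempdir(), "scores.tsv")
  for (s in list(c("a.png", "alice", 2), c("b.png", "alice", 0),
                 c("b.png", "bob", 1))) {
    upsert_review(store, s[1], s[2], as.integer(s[3]),
                  time = as.POSIXct("2024-01-01 10:00:00", tz = "UTC"))
  }
  dest <- file.path(withr::local_tempdir(), "reviews.csv")
  out <- export_reviews(store, dest)
  expect_equal(nrow(out), 3)
  csv <- utils::read.csv(dest)
  expect_equal(nrow(csv), 3)
  expect_setequal(names(csv),
                  c("snapshot_id", "rater", "score", "comment", "timestamp"))
  first <- readBin(dest, "raw", file.size(dest))
  export_reviews(store, dest)
  expect_identical(readBin(dest, "raw", file.size(dest)), first)

  empty_store <- file.path(withr::local_tempdir(), "none.tsv")
  dest2 <- file.path(withr::local_tempdir(), "empty.csv")
  expect_equal(nrow(export_reviews(empty_store, dest2)), 0)
  expect_equal(nrow(utils::read.csv(dest2)), 0)  # header-only file
})

test_that("the static gallery page lists every snapshot with badges", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    png::writePNG(matrix(0.5, 4, 4), file.path(dir, sprintf("s%d.png", i)))
  }
  manifest <- tibble::tibble(snapshot_id = sprintf("s%d.png", 1:3),
                             session_id = sprintf("S%d", 1:3),
                             subject_id = "A", T1 = c(TRUE, FALSE, TRUE))
  g <- load_gallery(dir, manifest)
  store <- file.path(dir, "scores.tsv")
  upsert_review(store, "s1.png", "alice", 2)
  out <- file.path(dir, "gallery.html")
  render_gallery_html(g, store, out)
  html <- paste(readLines(out), collapse = "\n")
  for (i in 1:3) expect_match(html, sprintf("s%d.png", i), fixed = TRUE)
  expect_match(html, "alice: 2", fixed = TRUE)
})
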