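test_that("read counts parse with separators and the display-cap marker", {
  p <- parse_read_count(c("532", "1,204", "100000+", "250000"), cap = 100000L)
  expect_identical(p$count, c(532L, 1204L, 100000L, 100000L))
  expect_identical(p$censored, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(parse_read_count(c("10", "n/a"), cap = 100000L), "record 2")
})

test_that("cap marker always yields count == cap with censored flag set", {
  raws <- c("99999+", "100000+", "1+", "100001")
  p <- parse_read_count(raws, cap = 100000L)
  expect_true(all(p$censored))
  expect_true(all(p$count == 100000L))
  # never count > cap with censored = FALSE
  vals <- c(0, 1, 99999, 100000, 500000)
  p2 <- parse_read_count(format(vals, scientific = FALSE, trim = TRUE),
                         cap = 100000L)
  expect_false(any(p2$count > 100000L))
  expect_true(all(p2$censored == (vals >= 1e5)))
})

test_that("corpus construction enforces its invariants", {
  expect_s3_class(tiny_corpus(), "corpus")
  expect_error(corpus(tiny_records()[, -2]), "title")
  expect_error(corpus(tiny_records(read_count = c(5L, -1L, 2L))), "read_count")
  expect_error(corpus(tiny_records(content_type = c(1L, 7L, 2L))), "content_type")
  expect_error(corpus(tiny_records(read_censored = c(TRUE, FALSE, FALSE))),
               "display cap")
  expect_error(corpus(tiny_records(), collection_date = "2020-01-01"),
               "collection_date")
  expect_error(corpus(tiny_records(), accounts = "someone_else"), "unknown account")
})

test_that("corpus CSV and JSON round-trips preserve all attributes", {
  rec <- tiny_records(4L,
    read_count = c(532L, 1204L, 100000L, 80L),
    read_censored = c(FALSE, FALSE, TRUE, FALSE),
    is_original = c(TRUE, FALSE, TRUE, TRUE),
    title = c("Flu alert!", "update, daily", "cases cases", "plain")
  )
  x <- corpus(rec, collection_date = as.Date("2020-04-07"))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_corpus(x, path, format = fmt)
    y <- read_corpus(path, format = fmt, collection_date = as.Date("2020-04-07"))
    expect_equal(as.data.frame(y$records), as.data.frame(x$records))
    expect_identical(n_posts(y), n_posts(x))
  }
})

test_that("corpus reader rejects malformed files informatively", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- tiny_records()
  x <- corpus(rec)
  write_corpus(x, path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  readr::write_csv(df[, setdiff(names(df), "title")], path)
  expect_error(read_corpus(path), "title")
  expect_error(read_corpus(withr::local_tempfile(fileext = ".csv")), "no such file")
})

test_that("column maps let non-canonical headers load", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- corpus(tiny_records())
  write_corpus(x, path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  names(df)[names(df) == "title"] <- "headline"
  readr::write_csv(df, path)
  y <- read_corpus(path, column_map = c(title = "headline"))
  expect_identical(y$records$title, x$records$title)
})

test_that("case series are sorted, validated and round-trip", {
  s <- case_series(c("2020-01-22", "2020-01-21"), c(15, 10))
  expect_identical(s$date, as.Date(c("2020-01-21", "2020-01-22")))
  expect_identical(s$new_cases, c(10L, 15L))
  expect_error(case_series(c("2020-01-21", "2020-01-21"), c(1, 2)), "duplicate")
  expect_error(case_series("2020-01-21", -1), "nonnegative")

  path <- withr::local_tempfile(fileext = ".csv")
  write_case_series(s, path)
  expect_equal(read_case_series(path), s)
})
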