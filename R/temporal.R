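#' Daily posting counts
#'
#' Counts posts per day over a contiguous, zero-filled date range.
#'
#' @param x A [corpus()].
#' @param accounts Optional character vector restricting to these accounts;
#'   unknown accounts are an error.
#' @param date_range Optional length-2 Date vector; defaults to the span of
#'   posting dates in the (unfiltered) corpus.
#' @return A tibble `date`, `posts` with one row per day; `sum(posts)`
#'   equals the number of filtered records inside the range.
#' @export
daily_counts <- function(x, accounts = NULL, date_range = NULL) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  if (!is.null(accounts)) {
    unknown <- setdiff(accounts, x$accounts)
    if (length(unknown) > 0L) {
      stop("unknown account(s) in filter: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    rec <- rec[rec$account_id %in% accounts, ]
  }
  dates <- as.Date(rec$posted_at, tz = "UTC")
  if (is.null(date_range)) {
    all_dates <- as.Date(x$records$posted_at, tz = "UTC")
    if (length(all_dates) == 0L) {
      return(tibble::tibble(date = as.Date(character()), posts = integer()))
    }
    date_range <- range(all_dates)
  }
  days <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  tab <- table(factor(as.character(dates), levels = as.character(days)))
  tibble::tibble(date = days, posts = as.integer(tab))
}

#' Hour-of-day posting profile
#'
#' @param x A [corpus()].
#' @param accounts Optional account filter (unknown accounts error).
#' @return An integer vector of length 24 named `"0"`..`"23"`; its sum is
#'   the number of filtered records. The profile's argmax is the peak
#'   posting hour.
#' @export
hourly_profile <- function(x, accounts = NULL) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  if (!is.null(accounts)) {
    unknown <- setdiff(accounts, x$accounts)
    if (length(unknown) > 0L) {
      stop("unknown account(s) in filter: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    rec <- rec[rec$account_id %in% accounts, ]
  }
  hour <- as.integer(format(rec$posted_at, "%H", tz = "UTC"))
  counts <- table(factor(hour, levels = 0:23))
  stats::setNames(as.integer(counts), 0:23)
}

#' Peak posting hour
#' @param profile A 24-vector of hourly counts, as from [hourly_profile()].
#' @return The hour (0-23) with the highest count (first on ties).
#' @export
peak_hour <- function(profile) {
  stopifnot(length(profile) == 24L)
  as.integer(which.max(profile) - 1L)
}

#' Per-period five-number summaries of a daily series
#'
#' Splits a daily count series into consecutive periods of `period_days`
#' days (the last may be partial) and summarizes each with the five-number
#' summary of its daily counts. Quartiles use the inclusive
#' linear-interpolation convention (`stats::quantile` type 7); box-plot
#' conventions differ, so the choice is stated here.
#'
#' @param series A tibble with columns `date` and a count column (`posts`
#'   or `new_cases`).
#' @param period_days Period length in days, `>= 1`.
#' @return A tibble `period`, `n_days`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
period_summary <- function(series, period_days) {
  stopifnot(is.data.frame(series), "date" %in% names(series))
  assert_scalar_number(period_days, "period_days", lower = 1)
  value_col <- setdiff(names(series), "date")[1L]
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  value <- series[[value_col]]
  period <- as.integer(series$date - min(series$date)) %/% as.integer(period_days) + 1L
  tibble::tibble(period = period, value = value) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      min = min(.data$value),
      q1 = unname(stats::quantile(.data$value, 0.25, type = 7)),
      median = unname(stats::median(.data$value)),
      q3 = unname(stats::quantile(.data$value, 0.75, type = 7)),
      max = max(.data$value),
      .groups = "drop"
    )
}

#' Pearson correlation between two daily series
#'
#' Aligns the two series on their common dates and computes the
#' product-moment correlation with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#' Typical use: daily posting volume against daily new confirmed cases over
#' the same period.
#'
#' @param a,b Tibbles with a `date` column and one count column each.
#' @return A tibble with `r`, `p_value`, `n` (number of paired days).
#' @export
correlate_series <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            "date" %in% names(a), "date" %in% names(b))
  va <- setdiff(names(a), "date")[1L]
  vb <- setdiff(names(b), "date")[1L]
  common <- intersect(as.character(a$date), as.character(b$date))
  n <- length(common)
  if (n < 3L) stop("need at least 3 paired days for a correlation", call. = FALSE)
  xa <- a[[va]][match(common, as.character(a$date))]
  xb <- b[[vb]][match(common, as.character(b$date))]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop("correlation undefined: one series is constant on the common dates",
         call. = FALSE)
  }
  ct <- stats::cor.test(xa, xb, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
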