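#' Single Tweets Communication Index (STCI)
#'
#' A per-post communication-power score in the WeChat Communication Index
#' (WCI) family, combining cumulative reads and likes both per-day and in
#' total on a log scale:
#'
#' \deqn{STCI = 10 \left[0.6\left(0.2\ln(R/d + 1) + 0.8\ln(R + 1)\right) +
#'   0.4\left(0.2\ln(10Z/d + 1) + 0.8\ln(10Z + 1)\right)\right]^2}
#'
#' where `R` is cumulative reads, `Z` cumulative likes (weighted tenfold so
#' likes and reads contribute on comparable log scales), and `d` the number
#' of days from posting to engagement collection. Reads carry 60% of the
#' weight and likes 40%; within each, the daily-average term carries 20%
#' and the cumulative term 80%. The score is 0 exactly when `R = Z = 0`,
#' strictly increasing in `R` and `Z`, and non-increasing in `d`.
#'
#' @param reads Nonnegative cumulative read counts (`R`).
#' @param likes Nonnegative cumulative like counts (`Z`).
#' @param days Days from posting to collection (`d`), `>= 1`.
#' @return Numeric vector of nonnegative scores.
#' @examples
#' stci(reads = 100, likes = 10, days = 5)
#' @export
stci <- function(reads, likes, days) {
  if (any(reads < 0) || any(likes < 0)) {
    stop("`reads` and `likes` must be nonnegative", call. = FALSE)
  }
  if (any(days < 1)) stop("`days` must be >= 1", call. = FALSE)
  read_term <- 0.2 * log(reads / days + 1) + 0.8 * log(reads + 1)
  like_term <- 0.2 * log(10 * likes / days + 1) + 0.8 * log(10 * likes + 1)
  10 * (0.6 * read_term + 0.4 * like_term)^2
}

#' Score every post in a corpus with the STCI
#'
#' Post age `d` is the day difference between the corpus collection date
#' and the posting date, floored at 1 so same-day collection is well
#' defined. Censored read counts are scored at the display cap — a lower
#' bound on the true score — and flagged in the output.
#'
#' @param x A [corpus()] with its collection date set.
#' @return A tibble sorted by descending score with columns `rank`,
#'   `account_id`, `title`, `reads`, `likes`, `days`, `read_censored`,
#'   `content_type`, `score`.
#' @export
score_corpus <- function(x) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  post_date <- as.Date(rec$posted_at, tz = "UTC")
  if (any(post_date > x$collection_date)) {
    stop("posting date after collection date", call. = FALSE)
  }
  d <- pmax(as.integer(x$collection_date - post_date), 1L)
  out <- tibble::tibble(
    account_id = rec$account_id,
    title = rec$title,
    reads = rec$read_count,
    likes = rec$like_count,
    days = d,
    read_censored = rec$read_censored,
    content_type = rec$content_type,
    score = stci(rec$read_count, rec$like_count, d)
  )
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Filter scored posts above an STCI threshold
#'
#' Keeps posts with `score` strictly greater than `threshold` (the
#' high-communication-power screen, conventionally at 800), preserving
#' rank order.
#'
#' @param scores Output of [score_corpus()].
#' @param threshold Strict lower bound on the score (default 800).
#' @return The qualifying subset, same columns and order.
#' @export
high_stci_filter <- function(scores, threshold = 800) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  assert_scalar_number(threshold, "threshold")
  scores[scores$score > threshold, , drop = FALSE]
}

#' Per-account engagement summary
#'
#' For each account: the fraction of its posts read strictly more than
#' `reads_over` times (computed on the displayed, possibly cap-censored
#' read value) and the arithmetic mean like count.
#'
#' @param x A [corpus()].
#' @param reads_over Strict read-count threshold (default 10,000).
#' @return A tibble `account_id`, `n`, `rate_over`, `avg_likes`.
#' @export
engagement_summary <- function(x, reads_over = 10000) {
  stopifnot(inherits(x, "corpus"))
  empty <- setdiff(x$accounts, unique(x$records$account_id))
  if (length(empty) > 0L) {
    stop("account(s) with zero posts: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  x$records |>
    dplyr::group_by(.data$account_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      rate_over = mean(.data$read_count > reads_over),
      avg_likes = mean(.data$like_count),
      .groups = "drop"
    )
}
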