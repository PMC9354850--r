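#' The six content types for emergency-period posts
#'
#' The taxonomy used throughout: 1 epidemic overview release, 2 epidemic
#' prevention and control measures, 3 science and disinformation,
#' 4 epidemic line assistance stories, 5 epidemic impact, 6 negative impact.
#'
#' @return A tibble with columns `code` (1-6) and `name`.
#' @export
content_types <- function() {
  tibble::tibble(
    code = 1:6,
    name = c("epidemic overview release",
             "epidemic prevention and control measures",
             "science and disinformation",
             "epidemic line assistance stories",
             "epidemic impact",
             "negative impact")
  )
}

#' Build a content-type lexicon classifier definition
#'
#' A rule-based stand-in for manual content coding: each type has a keyword
#' list; a title is assigned the type whose keywords it hits most often,
#' with ties broken by `priority` and zero hits handled by `fallback`.
#'
#' @param keywords List of 6 character vectors of keywords (normalized to
#'   lowercase).
#' @param priority Permutation of 1:6; earlier codes win ties.
#' @param fallback `"unclassified"` (zero-hit titles get `NA`) or an integer
#'   type code in 1..6 assigned to zero-hit titles.
#' @return A list of class `type_lexicon`.
#' @export
type_lexicon <- function(keywords = default_type_lexicons(),
                         priority = 1:6,
                         fallback = "unclassified") {
  if (length(keywords) != 6L || any(lengths(keywords) == 0L)) {
    stop("`keywords` must be 6 non-empty keyword vectors", call. = FALSE)
  }
  if (!identical(sort(as.integer(priority)), 1:6)) {
    stop("`priority` must be a permutation of 1:6", call. = FALSE)
  }
  if (!(identical(fallback, "unclassified") ||
        (is.numeric(fallback) && fallback %in% 1:6))) {
    stop("`fallback` must be \"unclassified\" or a type code 1..6", call. = FALSE)
  }
  structure(list(keywords = lapply(keywords, function(x) tolower(as.character(x))),
                 priority = as.integer(priority),
                 fallback = fallback),
            class = "type_lexicon")
}

#' Classify titles into content types by keyword hits
#'
#' Titles are normalized and whitespace-tokenized; each type's score is the
#' number of token occurrences hitting that type's keyword list. The
#' highest-scoring type wins; ties go to the type earliest in the lexicon's
#' priority order; titles with zero hits follow the fallback policy.
#'
#' @param titles Character vector of titles.
#' @param lexicon A [type_lexicon()].
#' @return Integer vector of type codes (`NA` for unclassified).
#' @export
classify_titles <- function(titles, lexicon = type_lexicon()) {
  stopifnot(inherits(lexicon, "type_lexicon"))
  tokens <- tokenize_titles(titles)
  prio_rank <- order(lexicon$priority)        # rank position of each code
  rank_of <- match(1:6, lexicon$priority)
  vapply(tokens, function(tok) {
    hits <- vapply(lexicon$keywords, function(kw) sum(tok %in% kw), numeric(1))
    if (all(hits == 0)) {
      if (identical(lexicon$fallback, "unclassified")) return(NA_integer_)
      return(as.integer(lexicon$fallback))
    }
    best <- which(hits == max(hits))
    as.integer(best[which.min(rank_of[best])])
  }, integer(1), USE.NAMES = FALSE)
}

#' Label a corpus with lexicon-classified content types
#'
#' @param x A [corpus()].
#' @param lexicon A [type_lexicon()].
#' @return The corpus with `content_type` replaced by the classifier's
#'   labels.
#' @export
classify_corpus <- function(x, lexicon = type_lexicon()) {
  stopifnot(inherits(x, "corpus"))
  x$records$content_type <- classify_titles(x$records$title, lexicon)
  x
}

#' Per-account content-type distribution
#'
#' The per-account percentage of posts in each of the six types, with the
#' underlying counts. Accounts in the corpus roster with no posts get an
#' all-zero row.
#'
#' @param x A fully labeled [corpus()] (no `NA` in `content_type`).
#' @return A tibble with columns `account_id`, `type` (1-6), `n`, `pct`;
#'   each account's six percentages sum to 100.
#' @export
type_distribution <- function(x) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  if (anyNA(rec$content_type)) {
    stop("corpus contains unlabeled records; classify first", call. = FALSE)
  }
  grid <- tidyr::expand_grid(account_id = x$accounts, type = 1:6)
  counts <- rec |>
    dplyr::count(.data$account_id, type = .data$content_type) |>
    dplyr::right_join(grid, by = c("account_id", "type")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(.data$account_id, .data$type)
  counts |>
    dplyr::group_by(.data$account_id) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup()
}

#' Weekly content-type proportions
#'
#' Bins posts into 7-day weeks anchored at `anchor_date` (the final week
#' may be partial) and returns each week's type proportions.
#'
#' @param x A fully labeled [corpus()].
#' @param anchor_date First day of week 1; defaults to the earliest posting
#'   date. Posts before it are an error.
#' @return A tibble `week`, `type`, `n`, `prop`; each non-empty week's six
#'   proportions sum to 1.
#' @export
weekly_type_proportions <- function(x, anchor_date = NULL) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  if (anyNA(rec$content_type)) {
    stop("corpus contains unlabeled records; classify first", call. = FALSE)
  }
  dates <- as.Date(rec$posted_at, tz = "UTC")
  if (is.null(anchor_date)) anchor_date <- min(dates)
  anchor_date <- as.Date(anchor_date)
  if (any(dates < anchor_date)) {
    stop("corpus contains posts before the anchor date", call. = FALSE)
  }
  week <- as.integer(dates - anchor_date) %/% 7L + 1L
  grid <- tidyr::expand_grid(week = seq_len(max(week)), type = 1:6)
  tibble::tibble(week = week, type = rec$content_type) |>
    dplyr::count(.data$week, .data$type) |>
    dplyr::right_join(grid, by = c("week", "type")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(.data$week, .data$type) |>
    dplyr::group_by(.data$week) |>
    dplyr::mutate(prop = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup()
}
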