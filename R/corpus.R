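#' Parse displayed read counts with a display cap
#'
#' Social platforms often stop displaying exact read counts above a cap
#' (100,000 on WeChat): larger values appear only as the cap, so stored
#' counts are lower bounds. This parser accepts digit strings with optional
#' thousands separators and an optional trailing `"+"` cap marker.
#'
#' @param raw Character (or numeric) vector of displayed read counts, e.g.
#'   `"532"`, `"1,204"`, `"100000+"`.
#' @param cap Positive integer display cap (default 100,000).
#' @return A list with integer `count` and logical `censored`, both the
#'   length of `raw`. A record is censored when it carries the `"+"` marker
#'   or its value is at or above `cap`; censored records return
#'   `count == cap` (a lower bound on the true reads).
#' @examples
#' parse_read_count(c("532", "1,204", "100000+"))
#' @export
parse_read_count <- function(raw, cap = 100000L) {
  assert_scalar_number(cap, "cap", lower = 1)
  raw_chr <- trimws(as.character(raw))
  plus <- grepl("\\+$", raw_chr)
  core <- gsub("[ ,]", "", sub("\\+$", "", raw_chr))
  ok <- grepl("^[0-9]+$", core)
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("unparseable read count at record %d: '%s'", bad, raw_chr[bad]),
         call. = FALSE)
  }
  value <- as.numeric(core)
  censored <- plus | value >= cap
  list(count = as.integer(ifelse(censored, cap, value)),
       censored = censored)
}

# Canonical record columns; `content_type` is optional on input.
corpus_columns <- function() {
  c("account_id", "title", "is_original", "read_count", "read_censored",
    "watch_count", "like_count", "comment_count", "posted_at",
    "article_url", "cover_url", "content_type")
}

#' Construct a validated post corpus
#'
#' A corpus holds one row per published post with the nine crawled
#' attributes (title, originality, reads, posting time, watches, likes,
#' comments, article and cover links) plus the posting account and an
#' optional content-type label (integer 1-6). The collection date — the day
#' engagement counts were read off the platform — is stored alongside the
#' records because per-post scores depend on post age at collection.
#'
#' @param records A data frame with columns `account_id`, `title`,
#'   `is_original`, `read_count`, `read_censored`, `watch_count`,
#'   `like_count`, `comment_count`, `posted_at` (POSIXct or parseable
#'   character, interpreted in UTC), `article_url`, `cover_url`, and
#'   optionally `content_type`.
#' @param collection_date Date the engagement counts were collected; must be
#'   on or after the last posting date. Defaults to the last posting date.
#' @param accounts Character vector of account ids; defaults to the accounts
#'   present in `records`. Every record's account must belong to it.
#' @param read_cap Display cap used for the censored-read invariant.
#' @return An object of class `corpus`: a list with `records` (tibble),
#'   `collection_date`, `accounts`, `read_cap`.
#' @export
corpus <- function(records, collection_date = NULL, accounts = NULL,
                   read_cap = 100000L) {
  records <- tibble::as_tibble(records)
  required <- setdiff(corpus_columns(), "content_type")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("corpus records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("content_type" %in% names(records))) {
    records$content_type <- NA_integer_
  }
  if (is.character(records$posted_at)) {
    records$posted_at <- parse_posted_at(records$posted_at)
  }
  if (!inherits(records$posted_at, "POSIXct")) {
    stop("`posted_at` must be POSIXct or a parseable datetime string",
         call. = FALSE)
  }
  records$account_id <- as.character(records$account_id)
  records$title <- as.character(records$title)
  records$is_original <- as.logical(records$is_original)
  records$read_censored <- as.logical(records$read_censored)
  for (col in c("read_count", "watch_count", "like_count", "comment_count",
                "content_type")) {
    records[[col]] <- as.integer(records[[col]])
  }
  records <- records[, corpus_columns()]

  counts <- c("read_count", "watch_count", "like_count", "comment_count")
  for (col in counts) {
    if (anyNA(records[[col]]) || any(records[[col]] < 0L)) {
      stop(sprintf("`%s` must be nonnegative and non-missing", col), call. = FALSE)
    }
  }
  if (any(records$read_censored & records$read_count != as.integer(read_cap))) {
    stop("censored records must carry read_count equal to the display cap (",
         read_cap, ")", call. = FALSE)
  }
  bad_type <- !is.na(records$content_type) &
    !(records$content_type %in% 1:6)
  if (any(bad_type)) {
    stop("`content_type`, when present, must be an integer in 1..6", call. = FALSE)
  }

  if (is.null(accounts)) {
    accounts <- sort(unique(records$account_id))
  }
  accounts <- as.character(accounts)
  unknown <- setdiff(records$account_id, accounts)
  if (length(unknown) > 0L) {
    stop("records reference unknown account(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  post_dates <- as.Date(records$posted_at, tz = "UTC")
  if (is.null(collection_date)) {
    collection_date <- if (nrow(records) > 0L) max(post_dates) else Sys.Date()
  }
  collection_date <- as.Date(collection_date)
  if (nrow(records) > 0L && collection_date < max(post_dates)) {
    stop("collection_date precedes the last posting date", call. = FALSE)
  }

  structure(
    list(records = records,
         collection_date = collection_date,
         accounts = accounts,
         read_cap = as.integer(read_cap)),
    class = "corpus"
  )
}

parse_posted_at <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    bad <- which(is.na(out))
    stop("unparseable posted_at timestamp at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d posts from %d accounts\n",
              nrow(x$records), length(x$accounts)))
  if (nrow(x$records) > 0L) {
    rng <- range(as.Date(x$records$posted_at, tz = "UTC"))
    cat(sprintf("  posted      %s .. %s\n", rng[1], rng[2]))
  }
  cat(sprintf("  collected   %s\n", x$collection_date))
  cat(sprintf("  censored    %d reads at cap %d\n",
              sum(x$records$read_censored), x$read_cap))
  invisible(x)
}

#' Number of posts in a corpus
#' @param x A `corpus`.
#' @export
n_posts <- function(x) {
  stopifnot(inherits(x, "corpus"))
  nrow(x$records)
}

#' Read a post corpus from CSV or JSON
#'
#' The file must provide the nine crawled attributes per post plus the
#' posting account. Read counts may be raw display strings (`"1,204"`,
#' `"100000+"`); they are parsed with [parse_read_count()] so the cap
#' marker becomes a `read_censored` flag. Header names can be remapped via
#' `column_map` so files with localized headers load without editing.
#'
#' @param path Path to the corpus file.
#' @param format `"csv"` (default; UTF-8 with header row) or `"json"`
#'   (array of objects).
#' @param column_map Named character vector mapping canonical column names
#'   (see [corpus()]) to the file's header names; `NULL` means headers
#'   already canonical. `read_censored` may be omitted from the file when
#'   read counts carry the `"+"` marker instead.
#' @param collection_date Passed to [corpus()].
#' @param read_cap Display cap for read-count parsing.
#' @return A validated [corpus()].
#' @export
read_corpus <- function(path, format = c("csv", "json"), column_map = NULL,
                        collection_date = NULL, read_cap = 100000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(out)) stop("JSON corpus must be an array of objects", call. = FALSE)
    out[] <- lapply(out, as.character)
    tibble::as_tibble(out)
  }
  if (nrow(df) == 0L) stop("empty corpus file: ", path, call. = FALSE)

  if (!is.null(column_map)) {
    present <- intersect(unname(column_map), names(df))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  required <- setdiff(corpus_columns(), c("content_type", "read_censored"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("corpus file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  parsed <- parse_read_count(df$read_count, cap = read_cap)
  df$read_count <- parsed$count
  if ("read_censored" %in% names(df)) {
    df$read_censored <- as.logical(df$read_censored) | parsed$censored
  } else {
    df$read_censored <- parsed$censored
  }
  df$is_original <- parse_flag(df$is_original)
  if ("content_type" %in% names(df)) {
    df$content_type <- suppressWarnings(as.integer(df$content_type))
  }
  corpus(df, collection_date = collection_date, read_cap = read_cap)
}

parse_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

#' Write a post corpus to CSV or JSON
#'
#' Censored read counts are written back in display form (`"100000+"`), so
#' a write/read round trip preserves every attribute including the
#' censoring flag.
#'
#' @param x A [corpus()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("csv", "json")) {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format)
  df <- x$records
  df$read_count <- ifelse(df$read_censored,
                          paste0(df$read_count, "+"),
                          as.character(df$read_count))
  df$posted_at <- format(df$posted_at, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = FALSE)
  }
  invisible(path)
}

#' Construct a validated daily case series
#'
#' @param dates Date vector (coerced with `as.Date`).
#' @param counts Nonnegative integer daily new-confirmed-case counts.
#' @return A tibble with columns `date` and `new_cases`, sorted by date.
#' @export
case_series <- function(dates, counts) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date in case series", call. = FALSE)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("case counts must be nonnegative and non-missing", call. = FALSE)
  }
  if (any(counts != floor(counts))) {
    stop("case counts must be integers", call. = FALSE)
  }
  if (anyDuplicated(dates)) {
    stop("duplicate date in case series: ",
         as.character(dates[duplicated(dates)][1L]), call. = FALSE)
  }
  ord <- order(dates)
  tibble::tibble(date = dates[ord], new_cases = as.integer(counts[ord]))
}

#' Read a daily new-confirmed-cases series
#'
#' Expects a two-column CSV `date,new_cases` with ISO-8601 dates. Rows are
#' sorted by date; duplicate dates and negative counts are rejected.
#'
#' @param path Path to the CSV file.
#' @return A [case_series()] tibble.
#' @export
read_case_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("date", "new_cases") %in% names(df))) {
    stop("case series file must have columns `date` and `new_cases`", call. = FALSE)
  }
  case_series(df$date, as.numeric(df$new_cases))
}

#' Write a daily case series to CSV
#' @param x A [case_series()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_series <- function(x, path) {
  stopifnot(all(c("date", "new_cases") %in% names(x)))
  readr::write_csv(x[, c("date", "new_cases")], path, progress = FALSE)
  invisible(path)
}
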