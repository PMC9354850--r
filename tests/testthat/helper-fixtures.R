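# Programmatic fixtures shared across test files.

# A minimal valid record tibble; override any column via `...`.
tiny_records <- function(n = 3L, ...) {
  out <- tibble::tibble(
    account_id = rep("acct_a", n),
    title = sprintf("title %d", seq_len(n)),
    is_original = rep(TRUE, n),
    read_count = rep(500L, n),
    read_censored = rep(FALSE, n),
    watch_count = rep(10L, n),
    like_count = rep(5L, n),
    comment_count = rep(2L, n),
    posted_at = as.POSIXct("2020-01-20 08:00:00", tz = "UTC") + 3600 * seq_len(n),
    article_url = sprintf("https://posts.example/a/%d", seq_len(n)),
    cover_url = sprintf("https://posts.example/c/%d", seq_len(n)),
    content_type = rep(1L, n)
  )
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}

tiny_corpus <- function(n = 3L, ...) {
  corpus(tiny_records(n, ...), collection_date = as.Date("2020-04-07"))
}

# Random whitespace-joined titles over a small vocabulary.
with_random_titles <- function(seed, n = 50L, vocab = sprintf("t%02d", 1:20)) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(2:6, 1L), replace = TRUE), collapse = " ")
  }, character(1))
}

# Brute-force co-occurrence oracle: double loop over titles and term pairs.
brute_force_cooccurrence <- function(titles, terms) {
  toks <- lapply(strsplit(tolower(titles), "[[:space:]]+"), unique)
  n <- length(terms)
  m <- matrix(0L, n, n, dimnames = list(terms, terms))
  for (t in toks) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (terms[i] %in% t && terms[j] %in% t) {
          m[i, j] <- m[i, j] + 1L
          m[j, i] <- m[j, i] + 1L
        }
      }
    }
  }
  m
}

# A small, fast generator setup for synthetic-recovery tests.
small_config <- function(total_volume = 1200, dup_rates = 5, ...) {
  generator_config(
    accounts = c(a = 1, b = 1, c = 1, d = 1),
    start_date = "2020-01-17", end_date = "2020-02-15",
    total_volume = total_volume, peak_day = 10, peak_height = 500,
    dup_rates = dup_rates, ...
  )
}
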