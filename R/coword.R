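#' Default stoplist for title tokenization
#'
#' Common function words removed before frequency counting; extend or
#' replace it for other languages or a part-of-speech-aware pipeline.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stoplist <- function() {
  c("the", "a", "an", "of", "to", "in", "and", "or", "for", "on", "with",
    "is", "are", "at", "by", "from", "as", "it", "its", "this", "that")
}

#' Tokenize titles
#'
#' Default tokenizer: [normalize_title()] then whitespace splitting, with
#' stoplist filtering. Any segmenter satisfying the same contract (a
#' function mapping one string to a character vector of tokens) can be
#' plugged in — e.g. a Chinese word segmenter — and the stoplist is applied
#' after it.
#'
#' @param titles Character vector.
#' @param tokenizer `NULL` for the default, or `function(title) -> tokens`.
#' @param stoplist Character vector of tokens to drop.
#' @return A list of character vectors, one per title (empty titles give
#'   empty vectors).
#' @export
tokenize_titles <- function(titles, tokenizer = NULL, stoplist = character()) {
  toks <- if (is.null(tokenizer)) {
    strsplit(normalize_title(titles), " ", fixed = TRUE)
  } else {
    lapply(as.character(titles), tokenizer)
  }
  stoplist <- tolower(stoplist)
  lapply(toks, function(t) {
    t <- t[nzchar(t)]
    if (length(stoplist) > 0L) t <- t[!(t %in% stoplist)]
    t
  })
}

#' Term occurrence frequencies across titles
#'
#' Counts every token occurrence (occurrence frequency, not document
#' frequency) across all titles after tokenization and stoplist filtering.
#'
#' @param x A [corpus()] or a character vector of titles.
#' @param tokenizer,stoplist Passed to [tokenize_titles()].
#' @return A tibble `term`, `freq` in descending frequency (ties by term).
#' @export
term_frequencies <- function(x, tokenizer = NULL, stoplist = character()) {
  titles <- if (inherits(x, "corpus")) x$records$title else as.character(x)
  toks <- unlist(tokenize_titles(titles, tokenizer, stoplist))
  if (length(toks) == 0L) return(tibble::tibble(term = character(), freq = integer()))
  tab <- table(toks)
  out <- tibble::tibble(term = names(tab), freq = as.integer(tab))
  out[order(-out$freq, out$term), ]
}

#' Select high-frequency terms
#'
#' Keeps terms whose frequency is strictly greater than `min_freq`, then
#' truncates to the `top_k` most frequent (ties broken lexicographically).
#'
#' @param freqs Output of [term_frequencies()].
#' @param min_freq Strict frequency floor (default 60).
#' @param top_k Maximum number of terms retained (default 100).
#' @return Character vector of selected terms, most frequent first.
#' @export
select_high_freq <- function(freqs, min_freq = 60, top_k = 100) {
  stopifnot(is.data.frame(freqs), all(c("term", "freq") %in% names(freqs)))
  if (top_k < 1) stop("`top_k` must be >= 1", call. = FALSE)
  keep <- freqs[freqs$freq > min_freq, ]
  keep <- keep[order(-keep$freq, keep$term), ]
  utils::head(keep$term, top_k)
}

#' Term co-occurrence matrix over titles
#'
#' Entry (A, B) is the number of titles in which both terms appear
#' (presence per title, not occurrence products). Symmetric with zero
#' diagonal.
#'
#' @param x A [corpus()] or character vector of titles.
#' @param terms Character vector of terms (e.g. from [select_high_freq()]).
#' @param tokenizer,stoplist Passed to [tokenize_titles()].
#' @return A [pair_matrix()] of integer co-occurrence counts.
#' @export
cooccurrence_matrix <- function(x, terms, tokenizer = NULL,
                                stoplist = character()) {
  if (length(terms) == 0L) stop("empty term list", call. = FALSE)
  terms <- as.character(terms)
  titles <- if (inherits(x, "corpus")) x$records$title else as.character(x)
  toks <- tokenize_titles(titles, tokenizer, stoplist)
  # titles x terms presence indicator; crossprod gives per-title pair counts
  pres <- vapply(toks, function(t) terms %in% t, logical(length(terms)))
  pres <- matrix(pres, nrow = length(terms))        # terms x titles
  m <- tcrossprod(pres * 1L)                        # terms x terms
  diag(m) <- 0
  storage.mode(m) <- "integer"
  pair_matrix(m, terms)
}

#' Ochiai similarity transform of a co-occurrence matrix
#'
#' Normalizes raw co-occurrence counts by the geometric mean of the two
#' terms' marginal frequencies:
#' \deqn{y_{AB} = X_{AB} / \sqrt{X_A \, X_B}}
#' which maps counts into `[0, 1]` and removes the raw frequency gap
#' between common and rare terms. Marginals `X_A` are total occurrence
#' frequencies while `X_AB` is per-title presence, so `X_AB <=
#' min(X_A, X_B)` and the bound holds.
#'
#' @param m A [pair_matrix()] of raw co-occurrence counts.
#' @param freqs A [term_frequencies()] tibble covering every matrix term
#'   with positive frequency.
#' @return A [pair_matrix()]-classed numeric matrix of Ochiai coefficients.
#' @export
ochiai_transform <- function(m, freqs) {
  stopifnot(inherits(m, "pair_matrix"))
  terms <- rownames(m)
  f <- freqs$freq[match(terms, freqs$term)]
  if (anyNA(f)) {
    stop("term(s) missing from the frequency table: ",
         paste(terms[is.na(f)], collapse = ", "), call. = FALSE)
  }
  if (any(f <= 0)) stop("zero frequency for a selected term", call. = FALSE)
  y <- unclass(m) / sqrt(outer(f, f))
  out <- pair_matrix(y, terms)
  out
}

#' Degree centrality of a co-word network
#'
#' Binary mode: each term's number of nonzero neighbors divided by `n - 1`.
#' Valued mode: each term's row sum of tie weights.
#'
#' @param m A [pair_matrix()] (raw counts or Ochiai values), `n >= 2`.
#' @param mode `"binary"` or `"valued"`.
#' @return A tibble `term`, `centrality`, descending.
#' @export
degree_centrality <- function(m, mode = c("binary", "valued")) {
  stopifnot(inherits(m, "pair_matrix"))
  mode <- match.arg(mode)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 terms", call. = FALSE)
  cent <- if (mode == "binary") rowSums(m > 0) / (n - 1) else rowSums(m)
  out <- tibble::tibble(term = rownames(m), centrality = unname(cent))
  out[order(-out$centrality, out$term), ]
}
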