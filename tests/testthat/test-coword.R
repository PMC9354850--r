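test_that("tokenization normalizes, splits and applies the stoplist", {
  expect_identical(tokenize_titles("flu alert flu")[[1]], c("flu", "alert", "flu"))
  expect_identical(tokenize_titles("flu alert flu", stoplist = "alert")[[1]],
                   c("flu", "flu"))
  expect_identical(tokenize_titles("")[[1]], character(0))

  # plugin tokenizer contract: any function string -> tokens
  bigrams <- function(s) substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  expect_identical(tokenize_titles("abc", tokenizer = bigrams)[[1]], c("ab", "bc"))
})

test_that("term frequencies count occurrences, not documents", {
  tf <- term_frequencies(c("a b", "a c", "a a"))
  expect_equal(tf$freq[tf$term == "a"], 4L)
  expect_equal(tf$freq[tf$term == "b"], 1L)
  expect_true(all(diff(tf$freq) <= 0))
  expect_equal(nrow(term_frequencies(character(0))), 0L)
})

test_that("generated titles tokenize back to the generator's emitted words", {
  g <- generate_corpus(small_config(), seed = 15)
  toks <- tokenize_titles(g$corpus$records$title)
  cfg <- small_config()
  expect_true(all(lengths(toks) == cfg$n_keywords + cfg$n_filler))
  vocab <- c(unlist(cfg$type_lexicons), sprintf("w%03d", seq_len(cfg$vocab_size)))
  expect_true(all(unlist(toks) %in% vocab))
})

test_that("high-frequency selection is strict with lexicographic tie-break", {
  tf <- tibble::tibble(term = c("a", "b", "c", "d"), freq = c(100L, 61L, 60L, 59L))
  expect_identical(select_high_freq(tf, min_freq = 60), c("a", "b"))
  expect_identical(select_high_freq(tf, min_freq = 0, top_k = 10),
                   c("a", "b", "c", "d"))
  expect_length(select_high_freq(tibble::tibble(term = letters, freq = rep(99L, 26)),
                                 min_freq = 0, top_k = 10), 10L)
  expect_error(select_high_freq(tf, top_k = 0), "top_k")
})

test_that("co-occurrence counts titles containing both terms", {
  m <- cooccurrence_matrix(c("a b", "a b", "a c"), terms = c("a", "b", "c"))
  expect_equal(m["a", "b"], 2L)
  expect_equal(m["a", "c"], 1L)
  expect_equal(m["b", "c"], 0L)
  expect_true(all(diag(unclass(m)) == 0))
  expect_error(cooccurrence_matrix("a b", terms = character(0)), "empty term")
})

test_that("ochiai coefficients match hand computations and stay in [0,1]", {
  # X_AB = 10, X_A = 100, X_B = 25 -> 10 / sqrt(2500) = 0.2
  m <- pair_matrix(matrix(c(0, 10, 10, 0), 2, 2), c("A", "B"))
  y <- ochiai_transform(m, tibble::tibble(term = c("A", "B"), freq = c(100L, 25L)))
  expect_equal(y["A", "B"], 0.2)

  # titles ["a b","a b","a c"]: X_ab = 2, X_a = 3, X_b = 2 -> 2/sqrt(6)
  titles <- c("a b", "a b", "a c")
  tf <- term_frequencies(titles)
  co <- cooccurrence_matrix(titles, terms = c("a", "b", "c"))
  y2 <- ochiai_transform(co, tf)
  expect_equal(y2["a", "b"], 2 / sqrt(6), tolerance = 1e-12)
  expect_equal(y2["b", "c"], 0)
  expect_true(all(y2 >= 0 & y2 <= 1))

  expect_error(ochiai_transform(co, tf[tf$term != "c", ]), "missing")
})

test_that("extending the diagonal with marginal frequencies gives self-similarity 1", {
  titles <- c("a b c", "a b", "b c", "a")
  tf <- term_frequencies(titles)
  co <- unclass(cooccurrence_matrix(titles, terms = tf$term))
  diag(co) <- tf$freq[match(rownames(co), tf$term)]
  y <- co / sqrt(outer(tf$freq[match(rownames(co), tf$term)],
                       tf$freq[match(colnames(co), tf$term)]))
  expect_equal(unname(diag(y)), rep(1, nrow(co)))
})

test_that("ochiai values stay in [0,1] over random corpora", {
  for (s in 1:5) {
    titles <- with_random_titles(seed = s, n = 60)
    tf <- term_frequencies(titles)
    terms <- utils::head(tf$term, 12)
    y <- ochiai_transform(cooccurrence_matrix(titles, terms), tf)
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("degree centrality identifies hubs in both modes", {
  # star: center tied to all 4 leaves
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m[1, 2:5] <- m[2:5, 1] <- 1
  cent <- degree_centrality(pair_matrix(m), mode = "binary")
  expect_equal(cent$centrality[cent$term == "a"], 1.0)
  expect_equal(cent$centrality[cent$term == "b"], 0.25)

  cv <- degree_centrality(pair_matrix(m), mode = "valued")
  expect_equal(cv$centrality[cv$term == "a"], 4)

  # a term planted in every title dominates centrality
  titles <- paste("hub", c("x y", "y z", "z q", "q x"))
  tf <- term_frequencies(titles)
  y <- ochiai_transform(cooccurrence_matrix(titles, tf$term), tf)
  top <- degree_centrality(y, mode = "valued")$term[1]
  expect_identical(top, "hub")
})
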