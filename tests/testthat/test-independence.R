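test_that("title normalization collapses case, punctuation and whitespace", {
  expect_identical(normalize_title("  Flu  Alert! "), "flu alert")
  expect_identical(normalize_title("flu-alert"), normalize_title("flu alert"))
  x <- c("A; B", "a b", "A.B")
  expect_true(length(unique(normalize_title(x))) == 1L)
})

test_that("pair matrices enforce symmetry, nonnegativity and zero diagonal", {
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(pair_matrix(m), "pair_matrix")
  expect_error(pair_matrix(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(pair_matrix(matrix(c(1, 2, 2, 0), 2, 2)), "diagonal")
  expect_error(pair_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
})

dup_corpus <- function(titles_by_account) {
  recs <- do.call(rbind, lapply(names(titles_by_account), function(a) {
    t <- titles_by_account[[a]]
    tiny_records(length(t), account_id = rep(a, length(t)), title = t)
  }))
  corpus(recs)
}

test_that("exact duplication counts matched title pairs between accounts", {
  x <- dup_corpus(list(one = c("A", "B", "C"), two = c("B", "C", "D")))
  m <- duplication_matrix(x)
  expect_equal(m["one", "two"], 2L)
  expect_equal(m["two", "one"], 2L)

  # multiplicities: each post matched at most once per counterpart account
  x2 <- dup_corpus(list(one = c("x", "x", "x"), two = c("x", "x")))
  expect_equal(duplication_matrix(x2)["one", "two"], 2L)

  expect_error(duplication_matrix(x, sim_threshold = 0), "sim_threshold")
  expect_error(duplication_matrix(dup_corpus(list(solo = "A"))), "2 accounts")
})

test_that("duplication is invariant under account-order permutation", {
  x1 <- dup_corpus(list(a = c("p q", "r s"), b = c("p q", "t u"), c = "r s"))
  x2 <- dup_corpus(list(c = "r s", b = c("p q", "t u"), a = c("p q", "r s")))
  m1 <- duplication_matrix(x1)
  m2 <- duplication_matrix(x2)
  labs <- rownames(m1)
  expect_equal(unclass(m1)[labs, labs], unclass(m2)[labs, labs])
})

test_that("similarity matcher agrees with exact matching on verbatim duplicates", {
  g <- generate_corpus(small_config(), seed = 9)
  me <- duplication_matrix(g$corpus, matcher = "exact")
  ms <- duplication_matrix(g$corpus, matcher = "similarity", sim_threshold = 1)
  expect_equal(unclass(me), unclass(ms))
})

test_that("strength sums are row sums reported in descending order", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 2
  m["a", "c"] <- m["c", "a"] <- 1
  st <- strength_sums(pair_matrix(m))
  expect_equal(st$strength, c(3, 2, 1))
  expect_equal(st$label, c("a", "b", "c"))
  # sum of strengths = 2 x sum of upper triangle
  expect_equal(sum(st$strength), 2 * sum(m[upper.tri(m)]))

  zero <- pair_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_true(all(strength_sums(zero)$strength == 0))
})

test_that("valued density is the mean off-diagonal tie value", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- m["b", "a"] <- 2
  m["a", "c"] <- m["c", "a"] <- 1
  pm <- pair_matrix(m)
  expect_equal(valued_density(pm), 1.0)
  expect_equal(valued_density(pm, mode = "binary"), 4 / 6)

  const <- matrix(7, 4, 4); diag(const) <- 0
  expect_equal(valued_density(pair_matrix(const, letters[1:4])), 7)
  expect_error(valued_density(pair_matrix(matrix(0, 1, 1, dimnames = list("a", "a")))),
               "2 nodes")
})

test_that("DL and edge-list exports are well-formed plain text", {
  m <- pair_matrix(matrix(c(0, 3, 3, 0), 2, 2), c("acct one", "acct two"))
  dl <- withr::local_tempfile(fileext = ".dl")
  write_dl(m, dl)
  lines <- readLines(dl)
  expect_match(lines[1], "DL N=2 FORMAT=FULLMATRIX")
  expect_true("\"acct one\"" %in% lines)
  expect_equal(lines[length(lines)], "3 0")

  el <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(m, el)
  edges <- readr::read_csv(el, show_col_types = FALSE)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$weight, 3)
})
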