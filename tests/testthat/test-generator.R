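test_that("epidemic curve generation is deterministic and shape-faithful", {
  cfg <- small_config()
  c1 <- generate_epidemic_curve(cfg, seed = 11)
  c2 <- generate_epidemic_curve(cfg, seed = 11)
  expect_identical(c1, c2)
  expect_true(all(c1$new_cases >= 0))

  flat <- generate_epidemic_curve(generator_config(peak_height = 0), seed = 5)
  expect_true(all(flat$new_cases == 0))
})

test_that("the mean curve peaks at the configured peak day", {
  cfg <- generator_config(peak_day = 20, peak_height = 300)
  total <- numeric(cfg$n_days)
  for (s in 1:300) {
    total <- total + generate_epidemic_curve(cfg, seed = s)$new_cases
  }
  expect_lte(abs(which.max(total) - 20L), 1L)
})

test_that("corpus generation is reproducible and seed-sensitive", {
  cfg <- small_config()
  g1 <- generate_corpus(cfg, seed = 7)
  g2 <- generate_corpus(cfg, seed = 7)
  expect_identical(g1$corpus$records, g2$corpus$records)
  expect_identical(g1$truth$dup_planted, g2$truth$dup_planted)
  g3 <- generate_corpus(cfg, seed = 8)
  expect_false(identical(g1$corpus$records, g3$corpus$records))

  # byte-identical corpus files for identical (config, seed)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus(g1$corpus, p1)
  write_corpus(g2$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero duplication rates yield no cross-account title overlap", {
  cfg <- small_config(dup_rates = 0)
  g <- generate_corpus(cfg, seed = 3)
  m <- duplication_matrix(g$corpus)
  expect_true(all(m == 0))
})

test_that("a perfectly coupled config gives sample correlation exactly 1", {
  cfg <- small_config(rho = 1)
  curve <- generate_epidemic_curve(cfg, seed = 2)
  posts <- generate_daily_post_counts(cfg, curve = curve, seed = 2)
  expect_equal(stats::cor(posts$posts, curve$new_cases), 1.0)
})

test_that("posting-hour histogram recovers the planted profile", {
  cfg <- generator_config(total_volume = 10000)
  g <- generate_corpus(cfg, seed = 19)
  prof <- hourly_profile(g$corpus) / n_posts(g$corpus)
  tv <- 0.5 * sum(abs(prof - cfg$hour_profile))
  expect_lt(tv, 0.02)
})

test_that("censoring rate rises with the read location parameter", {
  rates <- vapply(c(7, 8.5, 10), function(ml) {
    g <- generate_corpus(small_config(read_meanlog = ml), seed = 4)
    mean(g$corpus$records$read_censored)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("planted duplicate pairs exist verbatim in both accounts", {
  g <- generate_corpus(small_config(), seed = 12)
  planted <- g$truth$dup_planted
  m <- duplication_matrix(g$corpus)
  # measured overlap can only exceed planted via chance collisions
  expect_true(all(m[rownames(planted), colnames(planted)] >= planted))
})

test_that("generator configs validate probability and symmetry invariants", {
  expect_error(generator_config(hour_profile = rep(1, 24)), "sum to 1")
  expect_error(generator_config(rho = 1.5), "rho")
  expect_error(generator_config(start_date = "2020-01-17", end_date = "2020-01-17"),
               "degenerate")
  bad_dup <- matrix(1, 10, 10)
  expect_error(generator_config(dup_rates = bad_dup), "diagonal")
})
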