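#' Default posting-hour profile
#'
#' 24 probabilities (hour 0-23) emulating government health-account posting
#' behaviour: essentially no posts between midnight and 07:00, a dominant
#' 08:00 peak, a secondary afternoon rise and a late-evening (23:00) bump.
#'
#' @return Numeric vector of length 24 summing to 1.
#' @export
default_hour_profile <- function() {
  p <- c(rep(0.002, 8),               # 00:00-07:00, near-silent overnight
         0.20, 0.10, 0.07, 0.05,     # 08-11, morning peak at 08:00
         0.04, 0.03, 0.04, 0.05,     # 12-15
         0.07, 0.06, 0.04, 0.03,     # 16-19, after-hours secondary rise
         0.04, 0.05, 0.06, 0.054)    # 20-23, pre-bedtime bump
  p / sum(p)
}

#' Default content-type keyword lexicons
#'
#' Six pairwise-disjoint keyword lists, one per content type:
#' 1 epidemic overview release, 2 epidemic prevention and control measures,
#' 3 science and disinformation, 4 epidemic line assistance stories,
#' 5 epidemic impact, 6 negative impact. Disjointness makes lexicon
#' classification exact on generated corpora, which is what lets synthetic
#' tests use the planted type as ground truth.
#'
#' @return Named list of 6 lowercase character vectors.
#' @export
default_type_lexicons <- function() {
  list(
    `1` = c("cases", "confirmed", "tally", "briefing", "daily", "update",
            "figures", "report", "counts", "newly"),
    `2` = c("policy", "lockdown", "notice", "measures", "conference",
            "quarantine", "regulation", "directive", "mask", "checkpoint"),
    `3` = c("rumor", "myth", "facts", "science", "virus", "symptoms",
            "knowledge", "debunk", "prevention", "hygiene"),
    `4` = c("volunteer", "frontline", "tribute", "heroes", "stories",
            "donation", "nurses", "rescue", "moving", "salute"),
    `5` = c("reopening", "schools", "work", "resumption", "economy",
            "travel", "unsealing", "recovery", "factories", "traffic"),
    `6` = c("corruption", "concealment", "deception", "punish", "violation",
            "misconduct", "accountability", "fraud", "coverup", "negligence")
  )
}

#' Default week-by-week content-type mixture
#'
#' One row per 7-day week, columns are the six content types. The planted
#' trends mirror what outbreak coverage typically does over a ten-week
#' emergency: science/disinformation (type 3) dominates early and declines,
#' frontline assistance stories (type 4) rise, impact/reopening coverage
#' (type 5) only appears once restrictions ease (week 6 on), while overview
#' releases (1), control measures (2) and negative coverage (6) stay flat.
#'
#' @param n_weeks Number of weekly rows (default 11: ten full weeks plus a
#'   partial final week for a 75-day window).
#' @return An `n_weeks x 6` matrix, each row summing to 1.
#' @export
default_type_mixture <- function(n_weeks = 11L) {
  stopifnot(n_weeks >= 1L)
  w <- seq_len(n_weeks)
  frac <- if (n_weeks > 1L) (w - 1) / (n_weeks - 1) else 0
  t3 <- 0.36 - 0.22 * frac
  t4 <- 0.14 + 0.22 * frac
  t5 <- ifelse(w < 6, 0.01, 0.01 + 0.06 * (w - 5) / max(1, n_weeks - 5))
  m <- cbind(`1` = rep(0.18, n_weeks), `2` = rep(0.21, n_weeks),
             `3` = t3, `4` = t4, `5` = t5, `6` = rep(0.01, n_weeks))
  m / rowSums(m)
}

#' Default account roster and posting weights
#'
#' Ten provincial health-commission accounts with relative posting volumes
#' proportional to the published tweet counts for the ten accounts over
#' Jan 17 - Mar 31, 2020 (total 6,612 posts).
#'
#' @return Named numeric vector of weights summing to 1.
#' @export
default_account_weights <- function() {
  counts <- c(`Healthy Beijing` = 242, `Healthy Guangdong` = 1174,
              `Healthy Hubei` = 904, `Healthy Hunan` = 70,
              `Healthy Jiangsu` = 475, `Healthy Shanghai` = 360,
              `Healthy Sichuan official` = 771, `Healthy Tianjin` = 1586,
              `Healthy Zhejiang` = 543, `Chongqing Health and hygiene` = 487)
  counts / sum(counts)
}

#' Configuration for the synthetic-corpus generator
#'
#' Bundles every planted parameter: the epidemic-curve shape, the target
#' Pearson correlation between daily posting volume and daily cases, the
#' posting-hour profile, the week-varying content-type mixture and type
#' lexicons, cross-account duplicate rates, and the engagement
#' distributions. All randomness downstream is controlled by `seed`.
#'
#' @param accounts Named numeric vector of per-account posting weights
#'   (normalized internally). Default: [default_account_weights()].
#' @param start_date,end_date Corpus date range (default 2020-01-17 to
#'   2020-03-31, a 75-day window).
#' @param peak_day Day index (1-based from `start_date`) at which the
#'   expected epidemic curve peaks (default 28, late-first-month peak).
#' @param peak_width Log-scale width of the log-normal-shaped curve
#'   (default 0.45; larger means a broader epidemic wave).
#' @param peak_height Expected daily new cases at the peak (default 4000).
#' @param rho Target Pearson correlation, on the count scale, between daily
#'   total posts and daily new cases; in `[-1, 1]` (default 0.721).
#' @param total_volume Expected total number of posts over the date range
#'   (default 6612).
#' @param hour_profile 24-vector of posting-hour probabilities.
#' @param type_mixture Weeks-by-6 matrix of content-type probabilities; the
#'   last row is recycled if the range spans more weeks.
#' @param type_lexicons List of 6 keyword vectors used to build titles.
#' @param vocab_size,zipf_exponent Filler-word vocabulary size and Zipf
#'   (power-law) exponent for filler-word frequencies.
#' @param n_keywords,n_filler Number of type keywords and filler words per
#'   title.
#' @param dup_rates Symmetric zero-diagonal matrix of expected shared-title
#'   counts per account pair, or a single number applied to every pair
#'   (default 5).
#' @param read_meanlog,read_sdlog Log-normal parameters of the true read
#'   count (defaults 7.56 and 1.8, giving a mean near 9,680 reads).
#' @param p_like Per-read probability of a like (default 0.005).
#' @param read_cap Display cap applied to reads (default 100,000).
#' @param collection_lag Days between `end_date` and the engagement
#'   collection date (default 7).
#' @param seed Integer seed controlling all generation.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(accounts = default_account_weights(),
                             start_date = "2020-01-17",
                             end_date = "2020-03-31",
                             peak_day = 28,
                             peak_width = 0.45,
                             peak_height = 4000,
                             rho = 0.721,
                             total_volume = 6612,
                             hour_profile = default_hour_profile(),
                             type_mixture = NULL,
                             type_lexicons = default_type_lexicons(),
                             vocab_size = 400L,
                             zipf_exponent = 1.2,
                             n_keywords = 2L,
                             n_filler = 4L,
                             dup_rates = 5,
                             read_meanlog = 7.56,
                             read_sdlog = 1.8,
                             p_like = 0.005,
                             read_cap = 100000L,
                             collection_lag = 7L,
                             seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  n_days <- as.integer(end_date - start_date) + 1L
  if (n_days < 2L) stop("degenerate date range: need at least 2 days", call. = FALSE)

  if (is.null(names(accounts)) || anyNA(names(accounts))) {
    stop("`accounts` must be a named weight vector", call. = FALSE)
  }
  if (any(accounts < 0) || sum(accounts) <= 0) {
    stop("account weights must be nonnegative with positive sum", call. = FALSE)
  }
  accounts <- accounts / sum(accounts)

  n_weeks <- as.integer(ceiling(n_days / 7))
  if (is.null(type_mixture)) type_mixture <- default_type_mixture(n_weeks)
  type_mixture <- as.matrix(type_mixture)
  if (ncol(type_mixture) != 6L) stop("`type_mixture` must have 6 columns", call. = FALSE)
  for (i in seq_len(nrow(type_mixture))) {
    assert_prob_vector(type_mixture[i, ], sprintf("type_mixture[%d,]", i), len = 6L)
  }
  assert_prob_vector(hour_profile, "hour_profile", len = 24L)
  assert_scalar_number(rho, "rho", lower = -1, upper = 1)
  assert_scalar_number(peak_width, "peak_width", lower = 1e-6)
  assert_scalar_number(peak_height, "peak_height", lower = 0)
  assert_scalar_number(total_volume, "total_volume", lower = 1)
  assert_scalar_number(p_like, "p_like", lower = 0, upper = 1)

  if (length(type_lexicons) != 6L) stop("`type_lexicons` must have 6 entries", call. = FALSE)
  type_lexicons <- lapply(type_lexicons, function(x) tolower(as.character(x)))

  n_acc <- length(accounts)
  if (length(dup_rates) == 1L) {
    dup_rates <- matrix(dup_rates, n_acc, n_acc)
    diag(dup_rates) <- 0
  }
  dup_rates <- as.matrix(dup_rates)
  if (!isTRUE(all.equal(dup_rates, t(dup_rates))) || any(diag(dup_rates) != 0) ||
      any(dup_rates < 0)) {
    stop("`dup_rates` must be symmetric, nonnegative, with zero diagonal",
         call. = FALSE)
  }
  dimnames(dup_rates) <- list(names(accounts), names(accounts))

  structure(
    list(accounts = accounts, start_date = start_date, end_date = end_date,
         n_days = n_days, peak_day = peak_day, peak_width = peak_width,
         peak_height = peak_height, rho = rho, total_volume = total_volume,
         hour_profile = hour_profile, type_mixture = type_mixture,
         type_lexicons = type_lexicons, vocab_size = as.integer(vocab_size),
         zipf_exponent = zipf_exponent, n_keywords = as.integer(n_keywords),
         n_filler = as.integer(n_filler), dup_rates = dup_rates,
         read_meanlog = read_meanlog, read_sdlog = read_sdlog,
         p_like = p_like, read_cap = as.integer(read_cap),
         collection_lag = as.integer(collection_lag), seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d accounts, %s .. %s (%d days)\n",
              length(x$accounts), x$start_date, x$end_date, x$n_days))
  cat(sprintf("  planted rho %.3f, expected volume %.0f posts, read cap %d\n",
              x$rho, x$total_volume, x$read_cap))
  invisible(x)
}

# Expected (noise-free) epidemic-curve shape: log-normal in the day index,
# maximized exactly at `peak_day`.
curve_shape <- function(config) {
  t <- seq_len(config$n_days)
  config$peak_height *
    exp(-(log(t / config$peak_day))^2 / (2 * config$peak_width^2))
}

#' Generate a synthetic daily new-cases curve
#'
#' Daily counts are Poisson draws around a log-normal-shaped expectation
#' that rises quickly to a peak and decays — the canonical single-wave
#' outbreak profile. Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A [case_series()] tibble over the config's date range.
#' @export
generate_epidemic_curve <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  mu <- curve_shape(config)
  counts <- with_seed(seed, stats::rpois(config$n_days, mu))
  case_series(seq(config$start_date, config$end_date, by = "day"), counts)
}

# Calibrated coupling weights are a deterministic function of the config's
# curve/volume/rho fields; cache them so repeated generation from one config
# (e.g. many-seed recovery studies) pays for calibration once.
.coupling_cache <- new.env(parent = emptyenv())

# Calibrate the latent coupling weight `a` so that the Monte-Carlo mean of
# the count-scale Pearson correlation between generated posts and generated
# cases hits the target rho. Uses common random numbers across candidate
# `a` values (so the objective is smooth and monotone) and a fixed internal
# seed, making the calibrated value a property of the config alone.
calibrate_coupling <- function(config, n_sim = 40L) {
  key <- rlang::hash(list(config$n_days, config$peak_day, config$peak_width,
                          config$peak_height, config$total_volume,
                          config$rho, n_sim))
  cached <- .coupling_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- calibrate_coupling_impl(config, n_sim)
  .coupling_cache[[key]] <- a
  a
}

calibrate_coupling_impl <- function(config, n_sim = 40L) {
  target <- abs(config$rho)
  if (target == 0) return(0)
  mu <- curve_shape(config)
  if (max(mu) <= 0 || stats::sd(mu) == 0) return(0)
  n <- config$n_days
  lambda <- config$total_volume / n
  s <- scale(log(mu + 1))[, 1L]

  sims <- with_seed(20200117L, list(
    cases = matrix(stats::rpois(n_sim * n, rep(mu, each = n_sim)), nrow = n_sim),
    eps = matrix(stats::rnorm(n_sim * n), nrow = n_sim)
  ))
  mean_r <- function(a) {
    g <- (a * matrix(s, n_sim, n, byrow = TRUE) + sims$eps) / sqrt(a^2 + 1)
    posts <- matrix(stats::qpois(stats::pnorm(g), lambda), n_sim, n)
    r <- vapply(seq_len(n_sim), function(k) {
      if (stats::sd(posts[k, ]) == 0 || stats::sd(sims$cases[k, ]) == 0) 0
      else stats::cor(posts[k, ], sims$cases[k, ])
    }, numeric(1))
    mean(r)
  }
  upper <- 60
  if (mean_r(upper) < target) return(upper)
  stats::uniroot(function(a) mean_r(a) - target, c(0, upper), tol = 1e-3)$root
}

#' Generate daily posting totals correlated with an epidemic curve
#'
#' Plants a target Pearson correlation, on the count scale, between daily
#' total posts and daily new cases. Posts are Poisson-marginal counts driven
#' by a latent normal that blends the standardized log curve shape with
#' white noise; the blend weight is pre-calibrated by Monte Carlo so the
#' achieved count-scale correlation matches `config$rho` in expectation.
#' `|rho| = 1` is handled exactly: posts are an integer multiple of cases
#' (or of the reflected cases), so the sample correlation is exactly +-1.
#'
#' @param config A [generator_config()].
#' @param curve A [case_series()] over the config's date range; generated
#'   from `seed` when `NULL`.
#' @param seed Seed; defaults to `config$seed`.
#' @return A tibble `date`, `posts` (nonnegative integers).
#' @export
generate_daily_post_counts <- function(config, curve = NULL, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(curve)) curve <- generate_epidemic_curve(config, seed = seed)
  if (nrow(curve) != config$n_days) {
    stop("curve does not span the config's date range", call. = FALSE)
  }
  n <- config$n_days
  lambda <- config$total_volume / n
  cases <- curve$new_cases

  if (abs(config$rho) == 1) {
    base <- if (config$rho > 0) cases else max(cases) - cases
    k <- max(1L, as.integer(round(lambda / max(mean(base), 1))))
    posts <- as.integer(k * base)
  } else {
    a <- calibrate_coupling(config)
    if (config$rho < 0) a <- -a
    mu <- curve_shape(config)
    s <- if (stats::sd(mu) > 0) scale(log(mu + 1))[, 1L] else rep(0, n)
    posts <- with_seed(seed + 1L, {
      g <- (a * s + stats::rnorm(n)) / sqrt(a^2 + 1)
      as.integer(stats::qpois(stats::pnorm(g), lambda))
    })
  }
  tibble::tibble(date = curve$date, posts = posts)
}

# Draw titles: `n_keywords` draws from the type lexicon followed by
# `n_filler` Zipf-weighted filler words, whitespace-joined so the default
# whitespace tokenizer recovers the generating tokens exactly.
draw_titles <- function(types, config) {
  n <- length(types)
  vocab <- sprintf("w%03d", seq_len(config$vocab_size))
  vp <- zipf_probs(config$vocab_size, config$zipf_exponent)
  filler <- matrix(sample(vocab, n * config$n_filler, replace = TRUE, prob = vp),
                   nrow = n)
  kw <- matrix("", nrow = n, ncol = config$n_keywords)
  for (tt in 1:6) {
    idx <- which(types == tt)
    if (length(idx) == 0L) next
    lex <- config$type_lexicons[[tt]]
    kw[idx, ] <- sample(lex, length(idx) * config$n_keywords, replace = TRUE)
  }
  apply(cbind(kw, filler), 1L, paste, collapse = " ")
}

#' Generate a synthetic post corpus with planted ground truth
#'
#' Emulates a multi-account government-media corpus during an outbreak:
#' daily totals correlated with the epidemic curve at the planted `rho`,
#' posting hours drawn from the hour profile, content types from the
#' week-varying mixture, titles built from disjoint type lexicons plus
#' Zipf-distributed filler words, verbatim duplicate titles planted across
#' account pairs at the configured rates, log-normal reads censored at the
#' display cap, and likes binomially thinned from (uncensored) reads.
#'
#' Planted duplicates overwrite the titles of already-drawn posts (one in
#' each account of the pair), so daily totals — and hence the planted
#' correlation — are untouched by duplication.
#'
#' @param config A [generator_config()].
#' @param curve Optional [case_series()]; generated from `seed` when `NULL`.
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with elements `corpus` (a [corpus()], `content_type`
#'   filled with the planted type), `truth` (planted per-pair duplicate
#'   counts, planted rho and hour profile, the curve), and `curve`.
#' @export
generate_corpus <- function(config, curve = NULL, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(curve)) curve <- generate_epidemic_curve(config, seed = seed)
  daily <- generate_daily_post_counts(config, curve = curve, seed = seed)

  with_seed(seed + 2L, {
    n <- sum(daily$posts)
    if (n == 0L) stop("generated corpus is empty; increase total_volume", call. = FALSE)
    dates <- rep(daily$date, daily$posts)
    acc_names <- names(config$accounts)
    account <- sample(acc_names, n, replace = TRUE, prob = config$accounts)
    hour <- sample(0:23, n, replace = TRUE, prob = config$hour_profile)
    minute <- sample(0:59, n, replace = TRUE)

    week <- pmin(as.integer(dates - config$start_date) %/% 7L + 1L,
                 nrow(config$type_mixture))
    type <- integer(n)
    for (w in unique(week)) {
      idx <- which(week == w)
      type[idx] <- sample(1:6, length(idx), replace = TRUE,
                          prob = config$type_mixture[w, ])
    }
    title <- draw_titles(type, config)

    # Plant verbatim cross-account duplicates by overwriting title slots.
    n_acc <- length(acc_names)
    dup_planted <- matrix(0L, n_acc, n_acc,
                          dimnames = list(acc_names, acc_names))
    used <- logical(n)
    for (i in seq_len(n_acc - 1L)) {
      for (j in seq((i + 1L), n_acc)) {
        rate <- config$dup_rates[i, j]
        if (rate <= 0) next
        n_d <- stats::rpois(1L, rate)
        if (n_d == 0L) next
        free_i <- which(account == acc_names[i] & !used)
        free_j <- which(account == acc_names[j] & !used)
        n_d <- min(n_d, length(free_i), length(free_j))
        if (n_d == 0L) next
        pick_i <- sample(free_i, n_d)
        pick_j <- sample(free_j, n_d)
        dup_type <- sample(1:6, n_d, replace = TRUE)
        dup_title <- draw_titles(dup_type, config)
        title[pick_i] <- dup_title
        title[pick_j] <- dup_title
        type[pick_i] <- dup_type
        type[pick_j] <- dup_type
        used[c(pick_i, pick_j)] <- TRUE
        dup_planted[i, j] <- dup_planted[j, i] <- n_d
      }
    }

    reads_true <- floor(stats::rlnorm(n, config$read_meanlog, config$read_sdlog))
    censored <- reads_true >= config$read_cap
    read_count <- as.integer(pmin(reads_true, config$read_cap))
    like_count <- stats::rbinom(n, size = as.integer(pmin(reads_true, .Machine$integer.max)),
                                prob = config$p_like)
    watch_count <- stats::rbinom(n, size = read_count, prob = 0.02)
    comment_count <- stats::rbinom(n, size = like_count, prob = 0.3)
    is_original <- stats::runif(n) < 0.7
    is_original[used & duplicated(title)] <- FALSE   # the copying side of a pair

    posted_at <- as.POSIXct(paste0(format(dates), sprintf(" %02d:%02d:00", hour, minute)),
                            tz = "UTC")
    records <- tibble::tibble(
      account_id = account, title = title, is_original = is_original,
      read_count = read_count, read_censored = censored,
      watch_count = watch_count, like_count = like_count,
      comment_count = comment_count, posted_at = posted_at,
      article_url = sprintf("https://posts.example/a/%06d", seq_len(n)),
      cover_url = sprintf("https://posts.example/c/%06d", seq_len(n)),
      content_type = type
    )
    records <- records[order(records$posted_at, records$account_id), ]

    corp <- corpus(records,
                   collection_date = config$end_date + config$collection_lag,
                   accounts = acc_names, read_cap = config$read_cap)
    truth <- list(dup_planted = dup_planted, rho = config$rho,
                  hour_profile = config$hour_profile,
                  type_mixture = config$type_mixture, curve = curve)
    list(corpus = corp, truth = truth, curve = curve)
  })
}
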