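# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so callers'
#' random streams are unaffected.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }, add = TRUE)
  }
  set.seed(seed)
  expr
}

# Zipf (power-law) sampling probabilities over ranks 1..n.
zipf_probs <- function(n, exponent) {
  stopifnot(n >= 1, exponent >= 0)
  p <- (seq_len(n))^(-exponent)
  p / sum(p)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Sum-to-one check used for probability vectors in configs.
assert_prob_vector <- function(p, name, len = NULL, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("`%s` must be a nonnegative numeric vector", name), call. = FALSE)
  }
  if (!is.null(len) && length(p) != len) {
    stop(sprintf("`%s` must have length %d", name, len), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}
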