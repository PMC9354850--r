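#' Canonicalize a post title for duplicate matching
#'
#' Lowercases, strips punctuation, and collapses runs of whitespace so that
#' titles differing only in case, punctuation or spacing compare equal.
#'
#' @param title Character vector.
#' @return Character vector of canonical forms.
#' @export
normalize_title <- function(title) {
  x <- tolower(as.character(title))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Construct a labeled symmetric pair matrix
#'
#' The shared container for account-level duplicate counts and term-level
#' co-occurrence counts: symmetric, nonnegative, zero diagonal, with row
#' and column labels.
#'
#' @param values Square numeric matrix.
#' @param labels Row/column labels; defaults to existing dimnames.
#' @return A matrix of class `pair_matrix`.
#' @export
pair_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pair matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  if (any(values < 0)) stop("pair matrix entries must be nonnegative", call. = FALSE)
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE))) {
    stop("pair matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(values) != 0)) stop("pair matrix diagonal must be zero", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  class(values) <- c("pair_matrix", class(matrix()))
  values
}

#' Cross-account duplicated-title matrix
#'
#' Entry (i, j) counts matched title pairs between accounts i and j: posts
#' whose titles are identical after [normalize_title()] (`matcher =
#' "exact"`) or whose token Jaccard similarity reaches `sim_threshold`
#' (`matcher = "similarity"`). Each post is matched at most once per
#' counterpart account (greedy maximum matching by similarity, which for
#' exact matching reduces to `min` of the per-title multiplicities).
#'
#' The field reads this matrix as an (inverse) independence measure: the
#' more overlapping content two accounts share, the less independent their
#' output. The quantity computed here is overlap strength; independence is
#' its inverse ranking.
#'
#' @param x A [corpus()] with at least two accounts.
#' @param matcher `"exact"` (default) or `"similarity"`.
#' @param sim_threshold Token-Jaccard threshold in (0, 1] for the
#'   similarity matcher.
#' @return A [pair_matrix()] of integer counts labeled by account.
#' @export
duplication_matrix <- function(x, matcher = c("exact", "similarity"),
                               sim_threshold = 0.8) {
  stopifnot(inherits(x, "corpus"))
  matcher <- match.arg(matcher)
  if (length(x$accounts) < 2L) stop("need at least 2 accounts", call. = FALSE)
  if (sim_threshold <= 0 || sim_threshold > 1) {
    stop("`sim_threshold` must be in (0, 1]", call. = FALSE)
  }
  acc <- x$accounts
  n_acc <- length(acc)
  canon <- normalize_title(x$records$title)
  by_acc <- split(canon, factor(x$records$account_id, levels = acc))
  m <- matrix(0L, n_acc, n_acc, dimnames = list(acc, acc))

  for (i in seq_len(n_acc - 1L)) {
    for (j in seq((i + 1L), n_acc)) {
      ti <- by_acc[[i]]
      tj <- by_acc[[j]]
      if (length(ti) == 0L || length(tj) == 0L) next
      cnt <- if (matcher == "exact") {
        shared <- intersect(ti, tj)
        if (length(shared) == 0L) 0L else
          sum(vapply(shared, function(s) min(sum(ti == s), sum(tj == s)), integer(1)))
      } else {
        jaccard_match_count(ti, tj, sim_threshold)
      }
      m[i, j] <- m[j, i] <- as.integer(cnt)
    }
  }
  pair_matrix(m, acc)
}

# Greedy maximum matching on the bipartite token-Jaccard graph: sort all
# qualifying cross pairs by similarity and take each post at most once.
jaccard_match_count <- function(ti, tj, threshold) {
  tok_i <- strsplit(ti, " ", fixed = TRUE)
  tok_j <- strsplit(tj, " ", fixed = TRUE)
  sims <- NULL
  for (a in seq_along(tok_i)) {
    ta <- unique(tok_i[[a]])
    for (b in seq_along(tok_j)) {
      tb <- unique(tok_j[[b]])
      s <- length(intersect(ta, tb)) / length(union(ta, tb))
      if (s >= threshold) sims <- rbind(sims, c(a, b, s))
    }
  }
  if (is.null(sims)) return(0L)
  sims <- sims[order(-sims[, 3L]), , drop = FALSE]
  used_a <- logical(length(tok_i))
  used_b <- logical(length(tok_j))
  count <- 0L
  for (k in seq_len(nrow(sims))) {
    a <- sims[k, 1L]; b <- sims[k, 2L]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- used_b[b] <- TRUE
      count <- count + 1L
    }
  }
  count
}

#' Per-node strength sums of a pair matrix
#'
#' Row sums of the matrix — for the duplication matrix, each account's
#' total overlap strength with all other accounts (high strength = low
#' content independence).
#'
#' @param m A [pair_matrix()].
#' @return A tibble `label`, `strength`, sorted by descending strength.
#' @export
strength_sums <- function(m) {
  stopifnot(inherits(m, "pair_matrix"))
  out <- tibble::tibble(label = rownames(m), strength = unname(rowSums(m)))
  out[order(-out$strength, out$label), ]
}

#' Valued network density of a pair matrix
#'
#' Valued mode (the UCINET convention for weighted networks) is the mean of
#' the n(n-1) off-diagonal tie values; binary mode is the fraction of
#' off-diagonal pairs with a nonzero tie.
#'
#' @param m A [pair_matrix()] with `n >= 2` nodes.
#' @param mode `"valued"` (default) or `"binary"`.
#' @return A single number.
#' @export
valued_density <- function(m, mode = c("valued", "binary")) {
  stopifnot(inherits(m, "pair_matrix"))
  mode <- match.arg(mode)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  off <- m[row(m) != col(m)]
  if (mode == "valued") mean(off) else mean(off > 0)
}

#' Write a pair matrix in UCINET DL full-matrix format
#'
#' Plain-text DL file readable by UCINET and other sociometric tools.
#'
#' @param m A [pair_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dl <- function(m, path) {
  stopifnot(inherits(m, "pair_matrix"))
  n <- nrow(m)
  lines <- c(
    sprintf("DL N=%d FORMAT=FULLMATRIX DIAGONAL=PRESENT", n),
    "ROW LABELS:",
    sprintf("\"%s\"", rownames(m)),
    "COLUMN LABELS:",
    sprintf("\"%s\"", colnames(m)),
    "DATA:",
    apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                   collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a pair matrix as a CSV edge list
#'
#' One row per unordered pair with a nonzero tie: `source,target,weight`.
#'
#' @param m A [pair_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(m, path) {
  stopifnot(inherits(m, "pair_matrix"))
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  df <- tibble::tibble(
    source = rownames(m)[idx[, 1L]],
    target = colnames(m)[idx[, 2L]],
    weight = m[idx]
  )
  readr::write_csv(df[order(-df$weight, df$source, df$target), ], path,
                   progress = FALSE)
  invisible(path)
}
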