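#' Configuration for the end-to-end analysis pipeline
#'
#' @param corpus_path Path to a corpus CSV/JSON, or a [corpus()] object.
#' @param cases_path Optional path to a `date,new_cases` CSV (or a
#'   [case_series()] tibble) for the volume/case correlation.
#' @param output_dir Directory for the report bundle (created if needed).
#' @param lexicon A [type_lexicon()] used when `classify = TRUE`.
#' @param stoplist Stoplist for the co-word stage.
#' @param classify Re-label content types with the lexicon classifier
#'   (`TRUE`, default) or keep labels already present (`FALSE`).
#' @param stci_threshold High-communication screen threshold (default 800).
#' @param min_freq,top_k High-frequency-word selection (defaults 60, 100).
#' @param read_cap Display cap for read parsing (default 100,000).
#' @param reads_over Engagement-rate read threshold (default 10,000).
#' @param matcher,sim_threshold Duplicate matcher settings (see
#'   [duplication_matrix()]).
#' @param period_days Period length for the box-plot stage (default 30).
#' @param collection_date Optional override passed to [read_corpus()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_path, cases_path = NULL, output_dir,
                            lexicon = type_lexicon(),
                            stoplist = default_stoplist(),
                            classify = TRUE,
                            stci_threshold = 800, min_freq = 60, top_k = 100,
                            read_cap = 100000L, reads_over = 10000,
                            matcher = "exact", sim_threshold = 0.8,
                            period_days = 30L, collection_date = NULL) {
  for (nm in c("stci_threshold", "min_freq", "top_k", "read_cap",
               "reads_over", "period_days")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  structure(
    list(corpus_path = corpus_path, cases_path = cases_path,
         output_dir = output_dir, lexicon = lexicon, stoplist = stoplist,
         classify = classify, stci_threshold = stci_threshold,
         min_freq = min_freq, top_k = top_k, read_cap = as.integer(read_cap),
         reads_over = reads_over, matcher = matcher,
         sim_threshold = sim_threshold, period_days = as.integer(period_days),
         collection_date = collection_date),
    class = "pipeline_config"
  )
}

write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(m), check.names = FALSE))
  df <- tibble::add_column(df, label = rownames(m), .before = 1L)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates every analysis stage on one corpus: account and type
#' bookkeeping tables, per-account engagement, daily/hourly posting series
#' and period box-plot summaries, the posting-volume vs new-cases Pearson
#' correlation (when a case series is supplied), STCI scores with the
#' high-score screen, the cross-account duplication matrix with strength
#' sums and valued density, and the high-frequency-word co-occurrence
#' network with its Ochiai transform and centralities. All outputs are
#' plain CSV/JSON/DL files in `config$output_dir`; a `manifest.json`
#' records the package version, a config hash, per-stage record counts and
#' the conservation identities (per-account and per-type counts both
#' totalling the corpus size). The run is deterministic: re-running the
#' same config over the same inputs reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  corp <- if (inherits(config$corpus_path, "corpus")) config$corpus_path else
    read_corpus(config$corpus_path, collection_date = config$collection_date,
                read_cap = config$read_cap)
  n_total <- n_posts(corp)
  if (config$classify) corp <- classify_corpus(corp, config$lexicon)

  # Bookkeeping tables: both margins must total the corpus.
  account_counts <- corp$records |>
    dplyr::count(.data$account_id, name = "n_posts") |>
    dplyr::arrange(.data$account_id)
  type_counts <- corp$records |>
    dplyr::count(type = .data$content_type, name = "n_posts") |>
    dplyr::arrange(.data$type)
  if (sum(account_counts$n_posts) != n_total) {
    stop("stage account_counts: per-account counts do not total the corpus",
         call. = FALSE)
  }
  labeled <- !anyNA(corp$records$content_type)
  if (labeled && sum(type_counts$n_posts) != n_total) {
    stop("stage type_counts: per-type counts do not total the corpus",
         call. = FALSE)
  }
  readr::write_csv(account_counts, out("account_counts.csv"), progress = FALSE)
  readr::write_csv(type_counts, out("type_counts.csv"), progress = FALSE)

  engagement <- engagement_summary(corp, reads_over = config$reads_over)
  readr::write_csv(engagement, out("engagement.csv"), progress = FALSE)

  daily <- daily_counts(corp)
  hourly <- hourly_profile(corp)
  readr::write_csv(daily, out("daily_counts.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(hour = 0:23, posts = unname(hourly)),
                   out("hourly_profile.csv"), progress = FALSE)
  readr::write_csv(period_summary(daily, config$period_days),
                   out("period_summary.csv"), progress = FALSE)

  correlation <- NULL
  if (!is.null(config$cases_path)) {
    cases <- if (is.data.frame(config$cases_path)) config$cases_path else
      read_case_series(config$cases_path)
    correlation <- correlate_series(daily, cases)
    jsonlite::write_json(as.list(correlation), out("correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  type_dist <- weekly <- NULL
  if (labeled) {
    type_dist <- type_distribution(corp)
    weekly <- weekly_type_proportions(corp)
    readr::write_csv(type_dist, out("type_distribution.csv"), progress = FALSE)
    readr::write_csv(weekly, out("weekly_type_proportions.csv"), progress = FALSE)
  }

  scores <- score_corpus(corp)
  high <- high_stci_filter(scores, config$stci_threshold)
  readr::write_csv(scores, out("stci_scores.csv"), progress = FALSE)
  readr::write_csv(high, out("stci_high.csv"), progress = FALSE)
  high_by_account <- high |> dplyr::count(.data$account_id, name = "n_posts")
  high_by_type <- high |> dplyr::count(type = .data$content_type, name = "n_posts")
  readr::write_csv(high_by_account, out("stci_high_by_account.csv"), progress = FALSE)
  readr::write_csv(high_by_type, out("stci_high_by_type.csv"), progress = FALSE)

  dup <- duplication_matrix(corp, matcher = config$matcher,
                            sim_threshold = config$sim_threshold)
  write_matrix_csv(dup, out("duplication_matrix.csv"))
  write_dl(dup, out("duplication_matrix.dl"))
  write_edge_list(dup, out("duplication_edges.csv"))
  strengths <- strength_sums(dup)
  readr::write_csv(strengths, out("overlap_strengths.csv"), progress = FALSE)

  freqs <- term_frequencies(corp, stoplist = config$stoplist)
  readr::write_csv(freqs, out("term_frequencies.csv"), progress = FALSE)
  terms <- select_high_freq(freqs, config$min_freq, config$top_k)
  coword <- ochiai <- centrality <- NULL
  if (length(terms) >= 2L) {
    coword <- cooccurrence_matrix(corp, terms, stoplist = config$stoplist)
    ochiai <- ochiai_transform(coword, freqs)
    centrality <- degree_centrality(ochiai, mode = "valued")
    write_matrix_csv(coword, out("coword_counts.csv"))
    write_matrix_csv(ochiai, out("coword_ochiai.csv"))
    write_dl(coword, out("coword_counts.dl"))
    readr::write_csv(centrality, out("coword_centrality.csv"), progress = FALSE)
  }

  manifest <- list(
    package = "infodemix",
    version = as.character(utils::packageVersion("infodemix")),
    config_hash = rlang::hash(config[setdiff(names(config),
      c("corpus_path", "cases_path", "output_dir"))]),
    n_posts = n_total,
    n_accounts = length(corp$accounts),
    stage_counts = list(
      loaded = n_total,
      account_counts_total = sum(account_counts$n_posts),
      type_counts_total = if (labeled) sum(type_counts$n_posts) else NA,
      scored = nrow(scores),
      high_stci = nrow(high)
    ),
    duplication_density = valued_density(dup),
    coword_density = if (!is.null(ochiai)) valued_density(ochiai) else NA,
    n_high_freq_terms = length(terms)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(corpus = corp, account_counts = account_counts,
                 type_counts = type_counts, engagement = engagement,
                 daily = daily, hourly = hourly, correlation = correlation,
                 type_distribution = type_dist, weekly = weekly,
                 scores = scores, high = high, duplication = dup,
                 strengths = strengths, term_frequencies = freqs,
                 coword = coword, ochiai = ochiai, centrality = centrality,
                 manifest = manifest))
}
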