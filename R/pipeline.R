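#' End-to-end pipeline configuration
#'
#' @param corpus_source One of: a `conv_corpus` (already loaded), a
#'   [generator_config()] (generate synthetically), the name of a
#'   [default_scenarios()] scenario, or `list(transcript = , meta = )`
#'   file paths.
#' @param seed Integer seed governing every stochastic stage.
#' @param stop_words Stop-word lemmas for preprocessing (default none).
#' @param btm A [btm_config()]; defaults to K = 200 with `seed + 1`.
#' @param repetition A [repetition_config()] (window length l = 3).
#' @param grid_t,grid_n Candidate day-interval and call-interval centers
#'   for the grid search (defaults 4..13 and 3..12).
#' @param half_width Interval half-width M (default 3).
#' @param m_bonferroni Bonferroni family size (default: the feature batch
#'   size, 29 standard + 6 repetition features).
#' @param alpha Adjusted-p significance rule (default 0.01).
#' @param reference Reference significance patterns for the consistency
#'   report, or `NULL` to skip (default: the packaged reference).
#' @param out_dir Directory for TSV/JSON outputs, or `NULL` for none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus_source, seed = 1L,
                            stop_words = character(),
                            btm = NULL,
                            repetition = repetition_config(),
                            grid_t = 4:13, grid_n = 3:12,
                            half_width = 3L,
                            m_bonferroni = NULL, alpha = 0.01,
                            reference = load_reference_patterns(),
                            out_dir = NULL) {
  if (is.null(btm)) btm <- btm_config(K = 200L, seed = as.integer(seed) + 1L)
  structure(
    list(corpus_source = corpus_source, seed = as.integer(seed),
         stop_words = stop_words, btm = btm, repetition = repetition,
         grid_t = grid_t, grid_n = grid_n, half_width = as.integer(half_width),
         m_bonferroni = m_bonferroni, alpha = alpha, reference = reference,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

resolve_corpus <- function(config) {
  src <- config$corpus_source
  if (inherits(src, "conv_corpus")) {
    return(list(corpus = src, ground_truth = NULL))
  }
  if (inherits(src, "generator_config")) {
    gen <- generate_corpus(src)
    return(list(corpus = gen$corpus, ground_truth = gen$ground_truth))
  }
  if (is.character(src) && length(src) == 1L) {
    scen <- default_scenarios(seed = config$seed)
    if (!src %in% names(scen)) {
      stop(sprintf("unknown scenario '%s' (have: %s)", src,
                   paste(names(scen), collapse = ", ")), call. = FALSE)
    }
    gen <- generate_corpus(scen[[src]])
    return(list(corpus = gen$corpus, ground_truth = gen$ground_truth))
  }
  if (is.list(src) && !is.null(src$transcript)) {
    if (!file.exists(src$transcript)) {
      stop(sprintf("transcript file not found: %s", src$transcript), call. = FALSE)
    }
    return(list(corpus = read_corpus(src$transcript, src$meta), ground_truth = NULL))
  }
  stop("unrecognized corpus_source", call. = FALSE)
}

conv_key <- function(conv) paste(conv$participant_id, conv$call_index, sep = "#")

#' Run the full analysis pipeline
#'
#' Generate or load the corpus; preprocess; fit the biterm topic model on
#' all sentences; extract the 29 standard features plus within-conversation
#' word/topic repetition per conversation; grid-search the day- and
#' call-interval centers for the word and topic pair features; extract the
#' four pair features at their selected centers; rank all 35 features by
#' AUC-ROC with Cohen's d and Bonferroni-adjusted Student t p values; and,
#' when a reference is supplied, report significance-pattern consistency.
#' Re-running with the same config reproduces every numeric output.
#'
#' @param config A [pipeline_config()].
#' @return List with `ranking`, `curves` (per pair feature), `best_centers`,
#'   `samples` (the long feature table), `pairs` (pair tables at the
#'   selected centers), `consistency` (or `NULL`), `corpus`, `model`,
#'   `counts` and `manifest`. Written as TSV/JSON under `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  src <- with_stage("load_corpus", resolve_corpus(config))
  corpus <- src$corpus

  corpus <- with_stage("preprocess",
                       preprocess_corpus(corpus, config$stop_words, quiet = TRUE))

  model <- with_stage("fit_btm", {
    vocab <- build_vocab(corpus)
    biterms <- build_training_set(corpus, vocab)
    fit_btm(biterms, config$btm, vocab)
  })

  groups <- corpus$participants$group[match(
    vapply(corpus$conversations, `[[`, character(1), "participant_id"),
    corpus$participants$participant_id)]

  # per-conversation caches reused by single and pair features
  caches <- with_stage("topic_windows", {
    wins <- lapply(corpus$conversations, conversation_topic_windows,
                   model = model, l = config$repetition$l)
    streams <- lapply(corpus$conversations, conv_lemma_stream)
    keys <- vapply(corpus$conversations, conv_key, character(1))
    names(wins) <- names(streams) <- keys
    list(windows = wins, streams = streams)
  })

  single <- with_stage("single_features", {
    rows <- lapply(seq_along(corpus$conversations), function(i) {
      conv <- corpus$conversations[[i]]
      vals <- c(
        standard_features(conv),
        word_repetition_single = word_repetition_single(conv),
        topic_repetition_single = as.numeric(
          topic_repetition_single(conv, model, config$repetition,
                                  windows = caches$windows[[conv_key(conv)]]))
      )
      tibble::tibble(
        feature = names(vals), value = unname(vals),
        participant_id = conv$participant_id, sample_id = conv_key(conv),
        group = groups[i], unit = "conversation"
      )
    })
    dplyr::bind_rows(rows)
  })

  word_pair_fn <- function(a, b) {
    inverse_honore(c(caches$streams[[conv_key(a)]], caches$streams[[conv_key(b)]]))
  }
  topic_pair_fn <- function(a, b) {
    as.numeric(topic_repetition_pair(
      a, b, model, config$repetition,
      windows_a = caches$windows[[conv_key(a)]],
      windows_b = caches$windows[[conv_key(b)]]))
  }

  grid <- with_stage("grid_search", {
    list(
      word_days = grid_search_interval(corpus, word_pair_fn, config$grid_t,
                                       config$half_width, "days"),
      word_calls = grid_search_interval(corpus, word_pair_fn, config$grid_n,
                                        config$half_width, "calls"),
      topic_days = grid_search_interval(corpus, topic_pair_fn, config$grid_t,
                                        config$half_width, "days"),
      topic_calls = grid_search_interval(corpus, topic_pair_fn, config$grid_n,
                                         config$half_width, "calls")
    )
  })
  best_centers <- lapply(grid, `[[`, "best_center")

  pair_samples <- with_stage("pair_features", {
    specs <- list(
      word_repetition_pair_days = list(fn = word_pair_fn, mode = "days",
                                       center = best_centers$word_days),
      word_repetition_pair_calls = list(fn = word_pair_fn, mode = "calls",
                                        center = best_centers$word_calls),
      topic_repetition_pair_days = list(fn = topic_pair_fn, mode = "days",
                                        center = best_centers$topic_days),
      topic_repetition_pair_calls = list(fn = topic_pair_fn, mode = "calls",
                                         center = best_centers$topic_calls)
    )
    out <- list()
    pair_tables <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      pairs <- build_pairs(corpus, interval_window(sp$center, config$half_width, sp$mode))
      vals <- vapply(seq_len(nrow(pairs)), function(r) {
        sp$fn(corpus$conversations[[pairs$earlier[r]]],
              corpus$conversations[[pairs$later[r]]])
      }, numeric(1))
      pairs$value <- vals
      pair_tables[[nm]] <- pairs
      out[[nm]] <- tibble::tibble(
        feature = nm, value = vals,
        participant_id = pairs$participant_id,
        sample_id = paste0(nm, ":", pairs$earlier, "-", pairs$later),
        group = pair_groups(corpus, pairs), unit = "pair"
      )
    }
    list(samples = dplyr::bind_rows(out), tables = pair_tables)
  })

  samples <- dplyr::bind_rows(single, pair_samples$samples)

  ranking <- with_stage("rank_features", {
    rank_features(samples, m = config$m_bonferroni, alpha = config$alpha)
  })

  consistency <- if (!is.null(config$reference)) {
    with_stage("consistency_report",
               significance_pattern_report(ranking, config$reference,
                                           alpha = config$alpha))
  } else NULL

  counts <- list(
    n_conversations = length(corpus$conversations),
    n_participants = nrow(corpus$participants),
    n_dropped_sentences = sum(vapply(corpus$conversations, function(cv) {
      cv$n_dropped_sentences %||% 0L
    }, numeric(1))),
    n_skipped_windows = sum(vapply(caches$windows, function(w) {
      attr(w, "n_skipped") %||% 0L
    }, numeric(1))),
    n_features_ranked = nrow(ranking),
    n_features_skipped = length(attr(ranking, "skipped"))
  )

  manifest <- list(
    seed = config$seed,
    btm = unclass(config$btm),
    repetition = unclass(config$repetition),
    half_width = config$half_width,
    grid_t = config$grid_t, grid_n = config$grid_n,
    best_centers = best_centers,
    package_version = as.character(utils::packageVersion("convrep")),
    counts = counts
  )

  result <- list(
    ranking = ranking,
    curves = lapply(grid, `[[`, "curve"),
    best_centers = best_centers,
    samples = samples,
    pairs = pair_samples$tables,
    consistency = consistency,
    corpus = corpus,
    model = model,
    ground_truth = src$ground_truth,
    counts = counts,
    manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    with_stage("write_outputs", write_pipeline_outputs(result, config$out_dir))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$ranking, file.path(out_dir, "ranking.tsv"), progress = FALSE)
  readr::write_tsv(result$samples, file.path(out_dir, "features.tsv"), progress = FALSE)
  for (nm in names(result$curves)) {
    readr::write_tsv(result$curves[[nm]],
                     file.path(out_dir, paste0("curve_", nm, ".tsv")), progress = FALSE)
  }
  for (nm in names(result$pairs)) {
    readr::write_tsv(result$pairs[[nm]],
                     file.path(out_dir, paste0("pairs_", nm, ".tsv")), progress = FALSE)
  }
  if (!is.null(result$consistency)) {
    readr::write_tsv(result$consistency$table,
                     file.path(out_dir, "consistency.tsv"), progress = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
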