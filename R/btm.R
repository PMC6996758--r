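#' Build a vocabulary from a preprocessed corpus
#'
#' Collects the distinct lemmas of all filtered sentences into a dense
#' lemma/id bijection (id = position, 1-based).
#'
#' @param corpus A preprocessed `conv_corpus` (see [preprocess_corpus()]).
#' @return Character vector of lemmas with class `btm_vocab`; `length()` is
#'   the vocabulary size W.
#' @export
build_vocab <- function(corpus) {
  lemmas <- unlist(lapply(corpus$conversations, function(cv) {
    unlist(lapply(filtered_sentences(cv), `[[`, "lemma"), use.names = FALSE)
  }), use.names = FALSE)
  structure(sort(unique(lemmas)), class = "btm_vocab")
}

filtered_sentences <- function(conv) {
  conv$sentences_filtered %||%
    stop("conversation has not been preprocessed (no sentences_filtered)", call. = FALSE)
}

#' Map lemmas to vocabulary ids
#'
#' @param vocab A `btm_vocab`.
#' @param lemmas Character vector.
#' @return Integer ids; unseen lemmas are `NA`.
#' @export
word_ids <- function(vocab, lemmas) {
  match(lemmas, unclass(vocab))
}

#' Extract biterms from one short context
#'
#' All unordered position pairs of the context's word ids, canonicalized so
#' that `w1 <= w2`. A context with n tokens yields choose(n, 2) biterms;
#' duplicate lemmas keep their multiplicity, so `w1 == w2` biterms occur.
#'
#' @param token_ids Integer word ids of one sentence (or one window).
#' @return Integer matrix with rows `w1`, `w2` and one column per biterm
#'   (`2 x 0` for fewer than two tokens).
#' @export
extract_biterms <- function(token_ids) {
  token_ids <- as.integer(token_ids)
  n <- length(token_ids)
  if (n < 2L) {
    return(matrix(integer(0), nrow = 2, dimnames = list(c("w1", "w2"), NULL)))
  }
  pairs <- utils::combn(n, 2L)
  a <- token_ids[pairs[1L, ]]
  b <- token_ids[pairs[2L, ]]
  out <- rbind(w1 = pmin(a, b), w2 = pmax(a, b))
  out
}

#' Pool the biterms of every sentence of a corpus
#'
#' The training set is the union, with multiplicity, of per-sentence biterm
#' multisets over all filtered sentences of all conversations; the training
#' context unit is the sentence.
#'
#' @param corpus A preprocessed `conv_corpus`.
#' @param vocab A `btm_vocab` covering the corpus.
#' @return Integer matrix with rows `w1`, `w2`.
#' @export
build_training_set <- function(corpus, vocab) {
  if (length(corpus$conversations) == 0L) stop("empty corpus", call. = FALSE)
  mats <- lapply(corpus$conversations, function(cv) {
    sents <- filtered_sentences(cv)
    do.call(cbind, lapply(sents, function(s) extract_biterms(word_ids(vocab, s$lemma))))
  })
  out <- do.call(cbind, mats)
  if (is.null(out)) out <- matrix(integer(0), nrow = 2)
  rownames(out) <- c("w1", "w2")
  out
}

#' Configuration for the biterm topic model
#'
#' Defaults follow common collapsed-Gibbs practice for this model family:
#' symmetric priors `alpha = 50/K` on topics and `beta = 0.01` on words,
#' 500 sweeps with point estimates taken from the final state (`burn_in`
#' is retained for checkpoint bookkeeping).
#'
#' @param K Number of topics (>= 1; the analysis default is 200).
#' @param alpha,beta Positive symmetric Dirichlet hyperparameters.
#' @param n_iterations Positive number of Gibbs sweeps.
#' @param burn_in Nonnegative, less than `n_iterations`.
#' @param seed Integer RNG seed.
#' @return A `btm_config` list.
#' @export
btm_config <- function(K = 200L, alpha = 50 / K, beta = 0.01,
                       n_iterations = 500L, burn_in = 250L, seed = 1L) {
  cfg <- list(K = as.integer(K), alpha = alpha, beta = beta,
              n_iterations = as.integer(n_iterations),
              burn_in = as.integer(burn_in), seed = as.integer(seed))
  stopifnot(cfg$K >= 1L, cfg$alpha > 0, cfg$beta > 0,
            cfg$n_iterations >= 1L, cfg$burn_in >= 0L,
            cfg$burn_in < cfg$n_iterations)
  structure(cfg, class = "btm_config")
}

#' Fit a biterm topic model by collapsed Gibbs sampling
#'
#' Runs `n_iterations` sweeps in which every biterm's topic is resampled
#' from its collapsed conditional, then reads point estimates off the final
#' counts: `theta_k = (n_k + alpha) / (|B| + K alpha)` and
#' `phi_{w|k} = (n_wk + beta) / (2 n_k + W beta)`. Deterministic given
#' `config$seed`.
#'
#' @param biterms Integer biterm matrix from [build_training_set()].
#' @param config A [btm_config()].
#' @param vocab The `btm_vocab` the ids refer to.
#' @param checkpoint_iters Optional sweep numbers at which to store interim
#'   `(theta, phi)` snapshots (used e.g. for held-out likelihood curves).
#' @return A `btm_model`: list with `theta` (length K), `phi` (K x W
#'   row-stochastic matrix), `vocab`, `config`, `state` (final `z`, `n_k`,
#'   `n_wk`) and `checkpoints`.
#' @export
fit_btm <- function(biterms, config, vocab, checkpoint_iters = integer(0)) {
  stopifnot(inherits(config, "btm_config"))
  B <- ncol(biterms)
  if (B < 1L) stop("need at least one biterm", call. = FALSE)
  W <- length(vocab)
  if (any(biterms < 1L) || any(biterms > W)) {
    stop("biterm word ids outside vocabulary", call. = FALSE)
  }
  set.seed(config$seed)
  res <- btm_gibbs_cpp(biterms[1L, ], biterms[2L, ], W, config$K,
                       config$alpha, config$beta, config$n_iterations,
                       as.integer(checkpoint_iters))
  point_estimates <- function(n_k, n_wk) {
    theta <- (n_k + config$alpha) / (B + config$K * config$alpha)
    phi <- t(sweep(n_wk + config$beta, 2L, 2 * n_k + W * config$beta, "/"))
    dimnames(phi) <- list(NULL, unclass(vocab))
    list(theta = theta, phi = phi)
  }
  est <- point_estimates(res$n_k, res$n_wk)
  checkpoints <- lapply(res$checkpoints, function(ck) {
    c(list(iter = ck$iter, n_k = ck$n_k, n_wk = ck$n_wk),
      point_estimates(ck$n_k, ck$n_wk))
  })
  structure(
    list(theta = est$theta, phi = est$phi, vocab = vocab, config = config,
         state = list(z = res$z, n_k = res$n_k, n_wk = res$n_wk),
         checkpoints = checkpoints),
    class = "btm_model"
  )
}

#' @export
print.btm_model <- function(x, ...) {
  cat(sprintf("<btm_model> K = %d topics over W = %d words\n",
              x$config$K, length(x$vocab)))
  invisible(x)
}

#' Mean log-likelihood of biterms under a fitted model
#'
#' `P(b) = sum_k theta_k phi_{w1|k} phi_{w2|k}` per biterm.
#'
#' @param model A `btm_model` (or a checkpoint with `theta` and `phi`).
#' @param biterms Integer biterm matrix.
#' @return Mean log P(b).
#' @export
biterm_log_likelihood <- function(model, biterms) {
  p <- colSums(model$theta * model$phi[, biterms[1L, ], drop = FALSE] *
                 model$phi[, biterms[2L, ], drop = FALSE])
  mean(log(p))
}

#' Sliding sentence windows
#'
#' Windows of `l` consecutive elements at stride 1: a list of length L
#' yields `L - l + 1` windows. When `L < l` a single window containing all
#' L elements is returned with a warning.
#'
#' @param sentences Nonempty list (or vector) of per-sentence objects.
#' @param l Window length (>= 1).
#' @return List of windows, each a sublist of `sentences`.
#' @export
sliding_windows <- function(sentences, l) {
  stopifnot(l >= 1L)
  L <- length(sentences)
  if (L == 0L) stop("empty sentence list", call. = FALSE)
  sentences <- as.list(sentences)
  if (L < l) {
    warning(sprintf("only %d sentence(s) for window length %d; using one short window",
                    L, l), call. = FALSE)
    return(list(sentences))
  }
  lapply(seq_len(L - l + 1L), function(i) sentences[i:(i + l - 1L)])
}

#' Topic proportions of one sentence window
#'
#' Averages the per-biterm topic posteriors over the window's biterms:
#' `P(k | window) = mean_b P(k | b)` with
#' `P(k | b) propto theta_k phi_{w1|k} phi_{w2|k}`. Biterms are a
#' sentence-level notion — the sampler is trained on within-sentence
#' pairs — so when the window is given as a list of sentences, biterms are
#' extracted per sentence and pooled; word pairs never span sentences.
#'
#' @param model A fitted `btm_model`.
#' @param token_ids Integer word ids: either one vector (a single short
#'   context) or a list of per-sentence vectors (`NA` ids, i.e.
#'   out-of-vocabulary lemmas, are dropped).
#' @return Length-K probability vector, or `NULL` when no sentence of the
#'   window has two in-vocabulary tokens (the caller should skip and count
#'   it).
#' @export
infer_window_proportions <- function(model, token_ids) {
  if (!is.list(token_ids)) token_ids <- list(token_ids)
  bt <- do.call(cbind, lapply(token_ids, function(ids) {
    extract_biterms(ids[!is.na(ids)])
  }))
  if (is.null(bt) || ncol(bt) == 0L) return(NULL)
  m <- model$theta * model$phi[, bt[1L, ], drop = FALSE] *
    model$phi[, bt[2L, ], drop = FALSE]
  m <- sweep(m, 2L, colSums(m), "/")
  rowMeans(m)
}

#' Topic-proportion vectors for every window of a conversation
#'
#' Applies [sliding_windows()] to the filtered sentences and
#' [infer_window_proportions()] to each window; undefined windows (fewer
#' than two in-vocabulary tokens) are skipped, not zero-filled.
#'
#' @param model A fitted `btm_model`.
#' @param conv A preprocessed [conversation()].
#' @param l Window length in sentences.
#' @return Numeric matrix (windows x K) with attribute `n_skipped`; zero
#'   rows when no window is defined.
#' @export
conversation_topic_windows <- function(model, conv, l = 3L) {
  sents <- filtered_sentences(conv)
  if (length(sents) == 0L) {
    return(structure(matrix(numeric(0), ncol = model$config$K), n_skipped = 0L))
  }
  ids <- lapply(sents, function(s) word_ids(model$vocab, s$lemma))
  wins <- suppressWarnings(sliding_windows(ids, l))
  vecs <- lapply(wins, function(w) infer_window_proportions(model, w))
  skipped <- vapply(vecs, is.null, logical(1))
  out <- do.call(rbind, vecs[!skipped])
  if (is.null(out)) out <- matrix(numeric(0), ncol = model$config$K)
  structure(out, n_skipped = sum(skipped))
}
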