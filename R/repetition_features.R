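#' Configuration for the repetition features
#'
#' @param l Sliding-window length in sentences (analysis default 3).
#' @param epsilon Positive floor applied to the mean topic distance before
#'   inversion, so that identical windows give a finite, flagged value.
#' @return A `repetition_config` list.
#' @export
repetition_config <- function(l = 3L, epsilon = 1e-6) {
  stopifnot(l >= 1L, epsilon > 0)
  structure(list(l = as.integer(l), epsilon = epsilon),
            class = "repetition_config")
}

conv_lemma_stream <- function(conv) {
  unlist(lapply(filtered_sentences(conv), `[[`, "lemma"), use.names = FALSE)
}

inverse_honore <- function(lemmas) {
  V <- length(lemmas)
  if (V < 2L) return(NA_real_)
  type_tab <- table(lemmas)
  hs <- vocabulary_richness(list(V = V, U = length(type_tab),
                                 V_uni = sum(type_tab == 1L)))[["honore_statistic"]]
  if (!is.finite(hs)) 0 else 1 / hs
}

#' Word repetition within a single conversation
#'
#' The reciprocal of Honore's statistic on the conversation's filtered
#' lemma stream. A document of all-distinct words (infinite HS, no
#' repetition) scores exactly 0; more repeated vocabulary gives larger
#' values.
#'
#' @param conv A preprocessed [conversation()].
#' @return Nonnegative value, `NA` when fewer than two tokens.
#' @export
word_repetition_single <- function(conv) {
  inverse_honore(conv_lemma_stream(conv))
}

#' Word repetition across a conversation pair
#'
#' The two filtered lemma streams are concatenated and the reciprocal of
#' Honore's statistic is computed on the merged document, so words reused
#' across the two calls count as repetition.
#'
#' @param conv_a,conv_b Preprocessed [conversation()]s.
#' @return Nonnegative value, `NA` when the merged stream has fewer than
#'   two tokens.
#' @export
word_repetition_pair <- function(conv_a, conv_b) {
  inverse_honore(c(conv_lemma_stream(conv_a), conv_lemma_stream(conv_b)))
}

mean_pairwise_distance <- function(m) {
  # mean Euclidean distance over all unordered row pairs
  mean(stats::dist(m))
}

mean_cross_distance <- function(a, b) {
  # mean Euclidean distance over all (row of a) x (row of b) pairs
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  mean(sqrt(sq))
}

inverse_floored <- function(d, epsilon) {
  structure(1 / max(d, epsilon), capped = d < epsilon)
}

#' Topic repetition within a single conversation
#'
#' Topic-proportion vectors are inferred for every sliding `l`-sentence
#' window ([conversation_topic_windows()]); the feature is the reciprocal
#' of the mean Euclidean distance over all unordered window pairs
#' (overlapping windows included), floored at `epsilon`. Small distances
#' mean the conversation keeps returning to the same topics, so larger
#' feature values mean more topic repetition.
#'
#' @param conv A preprocessed [conversation()].
#' @param model A fitted `btm_model`.
#' @param config A [repetition_config()].
#' @param windows Optional precomputed window matrix (rows = windows), to
#'   avoid re-inference when scoring many pairs.
#' @return Nonnegative value with attribute `capped`; `NA` when fewer than
#'   two windows are defined.
#' @export
topic_repetition_single <- function(conv, model, config = repetition_config(),
                                    windows = NULL) {
  w <- windows %||% conversation_topic_windows(model, conv, config$l)
  if (nrow(w) < 2L) return(NA_real_)
  inverse_floored(mean_pairwise_distance(w), config$epsilon)
}

#' Topic repetition across a conversation pair
#'
#' Distances are computed only over cross pairs (one window from each
#' conversation, within-conversation pairs excluded) and the feature is
#' the reciprocal of their mean, floored at `epsilon`. Symmetric in its two
#' arguments.
#'
#' @param conv_a,conv_b Preprocessed [conversation()]s.
#' @param model A fitted `btm_model`.
#' @param config A [repetition_config()].
#' @param windows_a,windows_b Optional precomputed window matrices.
#' @return Nonnegative value with attribute `capped`; `NA` when either side
#'   has no defined window.
#' @export
topic_repetition_pair <- function(conv_a, conv_b, model,
                                  config = repetition_config(),
                                  windows_a = NULL, windows_b = NULL) {
  wa <- windows_a %||% conversation_topic_windows(model, conv_a, config$l)
  wb <- windows_b %||% conversation_topic_windows(model, conv_b, config$l)
  if (nrow(wa) < 1L || nrow(wb) < 1L) return(NA_real_)
  inverse_floored(mean_cross_distance(wa, wb), config$epsilon)
}
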