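ANALYZED_POS <- c("noun", "verb", "adjective", "pronoun", "adverb",
                  "auxiliary_verb", "conjunction")

#' Registry of the 29 standard linguistic features
#'
#' 14 part-of-speech features, 3 vocabulary-richness features, 7
#' syntactic-complexity features and 5 perseveration features. For the
#' dependency-rate slot of the syntactic set, the registry carries the
#' distance variant (`avg_dependency_distance_per_sentence`, total distance
#' over sentence count); the count variant
#' (`avg_dependencies_per_sentence`) is also computed by
#' [syntactic_features()] but sits outside the registry.
#'
#' @return Tibble with columns `feature` and `category` (29 rows).
#' @export
feature_registry <- function() {
  tibble::tibble(
    feature = c(
      "noun_frequency", "verb_frequency", "adjective_frequency",
      "auxiliary_verb_frequency", "conjunction_frequency",
      "noun_ratio", "verb_ratio", "adjective_ratio", "pronoun_ratio",
      "adverb_ratio", "auxiliary_verb_ratio", "conjunction_ratio",
      "noun_to_verb_ratio", "pronoun_to_noun_ratio",
      "type_token_ratio", "brunet_index", "honore_statistic",
      "mean_sentence_length", "sentence_count", "word_count",
      "character_count", "dependency_count",
      "avg_dependency_distance_per_sentence", "total_dependency_distance",
      "perseveration_prop_sim_zero", "perseveration_prop_dist_lt_030",
      "perseveration_prop_dist_lt_050", "perseveration_min_dist",
      "perseveration_mean_dist"
    ),
    category = rep(
      c("pos", "vocabulary_richness", "syntactic", "perseveration"),
      times = c(14L, 3L, 7L, 5L)
    )
  )
}

#' Token and type counts of a conversation
#'
#' Counts are taken on the filtered lemma stream: V total word tokens, U
#' distinct lemma types, V_uni types occurring exactly once (hapax
#' legomena), total surface characters, and per-tag token counts.
#'
#' @param conv A preprocessed [conversation()].
#' @return List with `V`, `U`, `V_uni`, `char_count`, `pos_counts` (named
#'   integer vector over [pos_tags()]).
#' @export
doc_counts <- function(conv) {
  sents <- filtered_sentences(conv)
  lemmas <- unlist(lapply(sents, `[[`, "lemma"), use.names = FALSE)
  surfaces <- unlist(lapply(sents, `[[`, "surface"), use.names = FALSE)
  pos <- unlist(lapply(sents, `[[`, "pos"), use.names = FALSE)
  tab <- table(factor(pos, levels = pos_tags()))
  type_tab <- table(lemmas)
  list(
    V = length(lemmas),
    U = length(type_tab),
    V_uni = sum(type_tab == 1L),
    char_count = sum(nchar(surfaces)),
    pos_counts = stats::setNames(as.integer(tab), names(tab))
  )
}

safe_ratio <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else num / den
}

#' Part-of-speech features (14)
#'
#' Raw frequencies of nouns, verbs, adjectives, auxiliary verbs and
#' conjunctions; token-count-normalized ratios of the seven analyzed tags;
#' and the noun-to-verb and pronoun-to-noun ratios. Ratios with a zero
#' denominator (including V = 0) are flagged as `NA`, never silently zero.
#'
#' @param conv A preprocessed [conversation()].
#' @return Named numeric vector of 14 values.
#' @export
pos_features <- function(conv) {
  dc <- doc_counts(conv)
  n <- dc$pos_counts
  V <- dc$V
  c(
    noun_frequency = as.numeric(n[["noun"]]),
    verb_frequency = as.numeric(n[["verb"]]),
    adjective_frequency = as.numeric(n[["adjective"]]),
    auxiliary_verb_frequency = as.numeric(n[["auxiliary_verb"]]),
    conjunction_frequency = as.numeric(n[["conjunction"]]),
    noun_ratio = safe_ratio(n[["noun"]], V),
    verb_ratio = safe_ratio(n[["verb"]], V),
    adjective_ratio = safe_ratio(n[["adjective"]], V),
    pronoun_ratio = safe_ratio(n[["pronoun"]], V),
    adverb_ratio = safe_ratio(n[["adverb"]], V),
    auxiliary_verb_ratio = safe_ratio(n[["auxiliary_verb"]], V),
    conjunction_ratio = safe_ratio(n[["conjunction"]], V),
    noun_to_verb_ratio = safe_ratio(n[["noun"]], n[["verb"]]),
    pronoun_to_noun_ratio = safe_ratio(n[["pronoun"]], n[["noun"]])
  )
}

#' Vocabulary-richness features (3)
#'
#' Type-token ratio `TTR = U/V`; Brunet's index `BI = V^(U^-0.165)`
#' (smaller = richer vocabulary); Honore's statistic
#' `HS = 100 log(V) / (1 - V_uni/U)`, which weights hapax legomena and is
#' `Inf` when every type is a hapax (`V_uni = U`). The logarithm is natural
#' by default; a base-10 option is provided since downstream ranking is
#' scale-invariant.
#'
#' @param counts Output of [doc_counts()], or a list with `V`, `U`, `V_uni`.
#' @param log_base `"natural"` (default) or `"10"`.
#' @return Named numeric vector `type_token_ratio`, `brunet_index`,
#'   `honore_statistic` (all `NA` when V < 2).
#' @export
vocabulary_richness <- function(counts, log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  V <- counts$V; U <- counts$U; V_uni <- counts$V_uni
  if (V < 2L) {
    return(c(type_token_ratio = NA_real_, brunet_index = NA_real_,
             honore_statistic = NA_real_))
  }
  lg <- if (log_base == "natural") log(V) else log10(V)
  hs <- if (V_uni == U) Inf else 100 * lg / (1 - V_uni / U)
  c(
    type_token_ratio = U / V,
    brunet_index = V^(U^-0.165),
    honore_statistic = hs
  )
}

sentence_dependencies <- function(sentence) {
  h <- sentence$head
  if (any(is.na(h))) return(NULL)  # unannotated sentence
  pos0 <- seq_len(nrow(sentence)) - 1L
  dep <- h != -1L
  list(count = sum(dep), distance = sum(abs(pos0[dep] - h[dep])))
}

#' Syntactic-complexity features (7 + 1)
#'
#' Length metrics on the filtered token stream (mean sentence length in
#' tokens, sentence count, word count, character count) and dependency
#' metrics on the *unfiltered* sentences, whose head indices refer to
#' original positions: total number of dependencies, total dependency
#' distance (sum over dependent-head pairs of their absolute positional
#' separation, root excluded) and average dependency distance per sentence.
#' The count-rate variant `avg_dependencies_per_sentence` is returned as an
#' eighth value outside the 29-feature registry. The three dependency
#' features are `NA` unless every sentence carries head annotation.
#'
#' @param conv A preprocessed [conversation()].
#' @return Named numeric vector of 8 values.
#' @export
syntactic_features <- function(conv) {
  dc <- doc_counts(conv)
  n_sent <- length(conv$sentences)
  deps <- lapply(conv$sentences, sentence_dependencies)
  if (any(vapply(deps, is.null, logical(1)))) {
    dep_count <- dep_dist <- NA_real_
  } else {
    dep_count <- sum(vapply(deps, `[[`, numeric(1), "count"))
    dep_dist <- sum(vapply(deps, `[[`, numeric(1), "distance"))
  }
  c(
    mean_sentence_length = safe_ratio(dc$V, n_sent),
    sentence_count = as.numeric(n_sent),
    word_count = as.numeric(dc$V),
    character_count = as.numeric(dc$char_count),
    dependency_count = dep_count,
    avg_dependency_distance_per_sentence = safe_ratio(dep_dist, n_sent),
    total_dependency_distance = dep_dist,
    avg_dependencies_per_sentence = safe_ratio(dep_count, n_sent)
  )
}

tfidf_matrix <- function(sentences) {
  lemmas <- lapply(sentences, `[[`, "lemma")
  vocab <- sort(unique(unlist(lemmas, use.names = FALSE)))
  S <- length(sentences)
  tf <- matrix(0, nrow = S, ncol = length(vocab))
  for (i in seq_len(S)) {
    tab <- table(lemmas[[i]])
    tf[i, match(names(tab), vocab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  # smoothed idf (ln(S/df) + 1): terms present in every sentence keep a
  # positive weight, so identical sentences score cosine similarity 1
  # instead of degenerating to the zero vector
  idf <- log(S / df) + 1
  sweep(tf, 2L, idf, "*")
}

cosine_similarity_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  sim <- tcrossprod(m) / outer(norms, norms)
  sim[!is.finite(sim)] <- 0  # zero vectors (all-ubiquitous words): similarity 0
  sim
}

#' Perseveration features (5)
#'
#' Sentences (filtered, nonempty) are embedded as TF-IDF vectors with the
#' conversation's own sentences as the document collection (raw term
#' counts, `idf = ln(S / df)`); cosine similarity is computed for every
#' unordered sentence pair and `d = 1 - similarity`. Reported: the
#' proportion of pairs with similarity exactly 0, the proportions with
#' distance below 0.3 and below 0.5, and the minimum and mean distance.
#' Larger values mean more repetition for the threshold proportions; the
#' thresholds can alternatively be applied to similarity via
#' `threshold_on = "similarity"` since the field is genuinely split on this
#' convention.
#'
#' @param conv A preprocessed [conversation()].
#' @param threshold_on Apply the 0.3/0.5 cutoffs to `"distance"` (default)
#'   or `"similarity"`.
#' @return Named numeric vector of 5 values (`NA` when fewer than two
#'   sentences survive preprocessing).
#' @export
perseveration_features <- function(conv, threshold_on = c("distance", "similarity")) {
  threshold_on <- match.arg(threshold_on)
  sents <- filtered_sentences(conv)
  out_names <- c("perseveration_prop_sim_zero", "perseveration_prop_dist_lt_030",
                 "perseveration_prop_dist_lt_050", "perseveration_min_dist",
                 "perseveration_mean_dist")
  if (length(sents) < 2L) {
    return(stats::setNames(rep(NA_real_, 5L), out_names))
  }
  sim <- cosine_similarity_matrix(tfidf_matrix(sents))
  pair_sim <- sim[upper.tri(sim)]
  pair_dist <- 1 - pair_sim
  thr_values <- if (threshold_on == "distance") pair_dist else pair_sim
  stats::setNames(c(
    mean(pair_sim == 0),
    mean(thr_values < 0.3),
    mean(thr_values < 0.5),
    min(pair_dist),
    mean(pair_dist)
  ), out_names)
}

#' All 29 standard features of one conversation
#'
#' Concatenates [pos_features()], [vocabulary_richness()],
#' [syntactic_features()] (registry subset) and [perseveration_features()],
#' in registry order.
#'
#' @param conv A preprocessed [conversation()].
#' @param ... Passed on to the component feature functions.
#' @return Named numeric vector of 29 values.
#' @export
standard_features <- function(conv, ...) {
  syn <- syntactic_features(conv)
  out <- c(
    pos_features(conv),
    vocabulary_richness(doc_counts(conv)),
    syn[setdiff(names(syn), "avg_dependencies_per_sentence")],
    perseveration_features(conv, ...)
  )
  out[feature_registry()$feature]
}
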