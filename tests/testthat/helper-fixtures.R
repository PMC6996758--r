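# in-code fixtures shared across test files

sent <- function(lemmas, pos, heads = rep(NA_integer_, length(lemmas)),
                 surface = lemmas) {
  data.frame(surface = surface, lemma = lemmas, pos = pos,
             head = as.integer(heads), stringsAsFactors = FALSE)
}

noun_sent <- function(lemmas) sent(lemmas, rep("noun", length(lemmas)))

# a preprocessed single conversation around a list of sentences
conv_fix <- function(sentences, pid = "P1", date = "2020-01-01", idx = 1L,
                     stop_words = character()) {
  preprocess_conversation(conversation(pid, date, idx, sentences), stop_words)
}

corpus_fix <- function(convs, groups = NULL) {
  pids <- unique(vapply(convs, `[[`, character(1), "participant_id"))
  if (is.null(groups)) groups <- rep("control", length(pids))
  conv_corpus(convs, tibble::tibble(participant_id = pids, group = groups))
}

random_sentence <- function(n_tokens, vocab = sprintf("w%02d", 1:30),
                            analyzed_only = FALSE) {
  tags <- if (analyzed_only) pos_tags()[1:7] else pos_tags()
  sent(sample(vocab, n_tokens, replace = TRUE),
       sample(tags, n_tokens, replace = TRUE))
}

# random valid corpus; chain dependency heads on ~half the conversations
random_corpus <- function(n_participants = 3L, max_calls = 4L) {
  convs <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    n_calls <- sample(1:max_calls, 1L)
    dates <- as.Date("2021-03-01") + cumsum(sample(1:9, n_calls, replace = TRUE))
    with_heads <- runif(1) < 0.5
    for (ci in seq_len(n_calls)) {
      n_sent <- sample(1:4, 1L)
      sentences <- lapply(seq_len(n_sent), function(s) {
        n_tok <- sample(2:6, 1L)
        out <- random_sentence(n_tok)
        if (with_heads) out$head <- c(-1L, seq_len(n_tok - 1L) - 1L)
        out
      })
      convs[[length(convs) + 1L]] <- conversation(pid, dates[ci], ci, sentences)
    }
  }
  corpus_fix(convs, groups = sample(c("control", "AD"), n_participants, replace = TRUE))
}

# independent Honore statistic used as an oracle (never calls package internals)
oracle_hs <- function(lemmas) {
  V <- length(lemmas)
  tab <- table(lemmas)
  U <- length(tab)
  V_uni <- sum(tab == 1)
  if (V_uni == U) return(Inf)
  100 * log(V) / (1 - V_uni / U)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
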