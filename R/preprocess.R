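#' Default sentence-final punctuation
#'
#' Japanese and ASCII sentence-final marks plus newline. The set is a
#' configuration input everywhere it is used.
#'
#' @return Character vector of single-character delimiters.
#' @export
default_punctuation <- function() {
  c("。", "．", "！", "？", "!", "?", "\n")
}

#' Split raw text into sentence spans
#'
#' Splits on the given single-character delimiters. Consecutive delimiters
#' produce no empty spans; text without any delimiter is one span. The
#' returned vector carries attributes `delimiters` (the delimiter run
#' following each span, possibly `""` for a trailing span) and `prefix`
#' (any leading delimiter run), so that
#' `paste0(prefix, paste0(spans, delimiters, collapse = ""))` reconstructs
#' the input exactly.
#'
#' @param raw_text Nonempty character scalar.
#' @param punctuation Nonempty character vector of delimiter characters.
#' @return Character vector of nonempty spans with reconstruction attributes.
#' @export
split_sentences <- function(raw_text, punctuation = default_punctuation()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  stopifnot(length(punctuation) >= 1L)
  chars <- strsplit(raw_text, "", fixed = TRUE)[[1]]
  is_delim <- chars %in% punctuation
  r <- rle(is_delim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- vapply(seq_along(r$values), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
  prefix <- ""
  if (r$values[1]) {
    prefix <- pieces[1]
    pieces <- pieces[-1]
    r$values <- r$values[-1]
  }
  spans <- pieces[!r$values]
  delims <- character(length(spans))
  if (length(pieces) > 0L) {
    span_pos <- which(!r$values)
    for (j in seq_along(span_pos)) {
      k <- span_pos[j] + 1L
      delims[j] <- if (k <= length(pieces)) pieces[k] else ""
    }
  }
  structure(spans, delimiters = delims, prefix = prefix)
}

#' Load a stop-word list
#'
#' One lemma per line, UTF-8; lookup downstream is exact match on the
#' lemma. The packaged default list holds common Japanese function lemmas
#' and is a configuration artifact, not part of any formula.
#'
#' @param path File path; default is the packaged list.
#' @return Character vector of lemmas.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_default.txt", package = "convrep")
  }
  out <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out[nzchar(trimws(out))]
}

#' Remove numerals, symbols and stop words from a sentence
#'
#' Tokens tagged `numeral` or `symbol` and tokens whose lemma is in
#' `stop_words` are dropped; order is preserved. Head indices are defined on
#' original positions, so they are invalidated (set to `NA`) in the filtered
#' output; dependency features are computed on the unfiltered sentence.
#' Idempotent.
#'
#' @param sentence Token data frame (see [conversation()]).
#' @param stop_words Character vector of lemmas to drop (exact match).
#' @return Filtered token data frame (possibly zero rows).
#' @export
filter_tokens <- function(sentence, stop_words = character()) {
  keep <- !(sentence$pos %in% POS_EXCLUDED) & !(sentence$lemma %in% stop_words)
  out <- sentence[keep, , drop = FALSE]
  out$head <- rep(NA_integer_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Preprocess one conversation
#'
#' Attaches `sentences_filtered`: the per-sentence output of
#' [filter_tokens()], dropping sentences emptied by filtering (their count
#' is recorded in the `n_dropped_sentences` field). The raw `sentences` are
#' kept for dependency features.
#'
#' @param conv A [conversation()].
#' @param stop_words Stop-word lemmas.
#' @return The conversation with `sentences_filtered` and
#'   `n_dropped_sentences` added.
#' @export
preprocess_conversation <- function(conv, stop_words = character()) {
  filtered <- lapply(conv$sentences, filter_tokens, stop_words = stop_words)
  empty <- vapply(filtered, nrow, integer(1)) == 0L
  conv$sentences_filtered <- filtered[!empty]
  conv$n_dropped_sentences <- sum(empty)
  conv
}

#' Preprocess a whole corpus
#'
#' @param corpus A `conv_corpus`.
#' @param stop_words Stop-word lemmas (default: none; pass
#'   [load_stopwords()] for the packaged list).
#' @param quiet Suppress the dropped-sentence message.
#' @return The corpus with every conversation preprocessed.
#' @export
preprocess_corpus <- function(corpus, stop_words = character(), quiet = FALSE) {
  corpus$conversations <- lapply(corpus$conversations, preprocess_conversation,
                                 stop_words = stop_words)
  dropped <- sum(vapply(corpus$conversations, `[[`, integer(1), "n_dropped_sentences"))
  if (dropped > 0L && !quiet) {
    message(sprintf("preprocess: %d sentence(s) emptied by filtering were dropped", dropped))
  }
  corpus
}
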