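#' Construct a single annotated conversation
#'
#' A conversation is one phone call's participant-side text, pre-segmented
#' into sentences of annotated tokens. Each sentence is a data frame with
#' columns `surface`, `lemma`, `pos` (one of [pos_tags()]) and `head`
#' (0-based index of the syntactic head within the sentence, `-1` for the
#' root, `NA` when no dependency annotation is available).
#'
#' @param participant_id Character scalar identifying the speaker.
#' @param date Calendar date of the call (`Date` or ISO-8601 string).
#' @param call_index 1-based ordinal of this call within the participant's
#'   chronology.
#' @param sentences List of token data frames as described above.
#' @return A `conversation` object (a list).
#' @export
conversation <- function(participant_id, date, call_index, sentences) {
  structure(
    list(
      participant_id = as.character(participant_id),
      date = as.Date(date),
      call_index = as.integer(call_index),
      sentences = sentences
    ),
    class = "conversation"
  )
}

#' @export
print.conversation <- function(x, ...) {
  cat(sprintf(
    "<conversation> %s call %d on %s: %d sentence(s)\n",
    x$participant_id, x$call_index, format(x$date), length(x$sentences)
  ))
  invisible(x)
}

#' Construct a conversation corpus
#'
#' @param conversations List of [conversation()] objects.
#' @param participants Tibble of participant metadata with at least
#'   `participant_id` and `group` (`"control"` or `"AD"`) columns; the
#'   demographics fixture columns (`sex`, `age_band`, `follow_up_months`,
#'   `n_calls`, `mean_call_minutes`, ...) are carried when present.
#' @param validate Check corpus invariants (default `TRUE`).
#' @return A `conv_corpus` object.
#' @export
conv_corpus <- function(conversations, participants, validate = TRUE) {
  corpus <- structure(
    list(conversations = conversations, participants = tibble::as_tibble(participants)),
    class = "conv_corpus"
  )
  if (validate) validate_corpus(corpus)
  corpus
}

#' @export
print.conv_corpus <- function(x, ...) {
  cat(sprintf(
    "<conv_corpus> %d conversation(s) from %d participant(s)\n",
    length(x$conversations), nrow(x$participants)
  ))
  invisible(x)
}

token_sentence <- function(surface, lemma = surface, pos, head = NA_integer_) {
  data.frame(
    surface = as.character(surface),
    lemma = as.character(lemma),
    pos = as.character(pos),
    head = as.integer(head),
    stringsAsFactors = FALSE
  )
}

validate_sentence <- function(s, where) {
  if (!is.data.frame(s) || nrow(s) < 1L) {
    stop(where, ": each sentence must be a data frame with at least one token", call. = FALSE)
  }
  need <- c("surface", "lemma", "pos", "head")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0L) {
    stop(where, ": sentence missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(s$surface))) stop(where, ": empty token surface", call. = FALSE)
  bad_pos <- setdiff(unique(s$pos), pos_tags())
  if (length(bad_pos) > 0L) {
    stop(where, ": unknown pos tag(s) ", paste(bad_pos, collapse = ", "), call. = FALSE)
  }
  n <- nrow(s)
  h <- s$head
  ok <- is.na(h) | h == -1L | (h >= 0L & h < n & h != seq_len(n) - 1L)
  if (!all(ok)) {
    stop(where, ": invalid head index (out of range or self-referential)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a conversation corpus
#'
#' Checks every structural invariant: sentences are nonempty token frames
#' with known pos tags and valid head indices; per participant, call dates
#' are unique and `call_index` increases strictly with date; every
#' conversation's participant appears in the metadata table; when metadata
#' carries `n_calls` and the participant has attached conversations, the
#' counts agree.
#'
#' @param corpus A `conv_corpus`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "conv_corpus"))
  if (!all(c("participant_id", "group") %in% names(corpus$participants))) {
    stop("participants table must have participant_id and group columns", call. = FALSE)
  }
  known <- corpus$participants$participant_id
  for (i in seq_along(corpus$conversations)) {
    conv <- corpus$conversations[[i]]
    where <- sprintf("conversation %d (%s)", i, conv$participant_id)
    if (!conv$participant_id %in% known) {
      stop(where, ": participant_id not in participants table", call. = FALSE)
    }
    if (length(conv$sentences) < 1L) stop(where, ": no sentences", call. = FALSE)
    for (s in conv$sentences) validate_sentence(s, where)
  }
  pid <- vapply(corpus$conversations, `[[`, character(1), "participant_id")
  for (p in unique(pid)) {
    convs <- corpus$conversations[pid == p]
    dates <- as.Date(vapply(convs, function(cv) as.character(cv$date), character(1)))
    idx <- vapply(convs, `[[`, integer(1), "call_index")
    if (anyDuplicated(dates)) {
      stop(sprintf("participant %s: duplicate call dates", p), call. = FALSE)
    }
    ord <- order(idx)
    if (is.unsorted(dates[ord], strictly = TRUE)) {
      stop(sprintf("participant %s: call_index not strictly increasing with date", p),
           call. = FALSE)
    }
    if ("n_calls" %in% names(corpus$participants)) {
      nc <- corpus$participants$n_calls[match(p, known)]
      if (!is.na(nc) && nc != length(convs)) {
        stop(sprintf("participant %s: n_calls (%d) != attached conversations (%d)",
                     p, nc, length(convs)), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

conv_to_json <- function(conv) {
  sent_list <- lapply(conv$sentences, function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      tok <- list(surface = s$surface[i], lemma = s$lemma[i], pos = s$pos[i])
      if (!is.na(s$head[i])) tok$head <- s$head[i]
      tok
    })
  })
  jsonlite::toJSON(
    list(
      participant_id = conv$participant_id,
      date = format(conv$date, "%Y-%m-%d"),
      sentences = sent_list
    ),
    auto_unbox = TRUE
  )
}

#' Write a corpus to JSON Lines (+ optional metadata table)
#'
#' One JSON object per line per conversation with keys `participant_id`,
#' `date` (ISO-8601) and `sentences` (array of arrays of token objects with
#' keys `surface`, `lemma`, `pos` and, when annotated, `head`). `call_index`
#' is not serialized; it is reassigned by date order on load.
#'
#' @param corpus A validated `conv_corpus`.
#' @param transcript_path Output JSON Lines file.
#' @param meta_path Optional TSV path for the participants table.
#' @return `transcript_path` invisibly.
#' @export
write_corpus <- function(corpus, transcript_path, meta_path = NULL) {
  validate_corpus(corpus)
  lines <- vapply(corpus$conversations, function(cv) as.character(conv_to_json(cv)),
                  character(1))
  con <- file(transcript_path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, useBytes = TRUE)
  if (!is.null(meta_path)) {
    readr::write_tsv(corpus$participants, meta_path, progress = FALSE)
  }
  invisible(transcript_path)
}

parse_token <- function(tok, line_no) {
  for (f in c("surface", "lemma", "pos")) {
    if (is.null(tok[[f]])) {
      stop(sprintf("line %d: token missing required field '%s'", line_no, f),
           call. = FALSE)
    }
  }
  list(
    surface = as.character(tok$surface),
    lemma = as.character(tok$lemma),
    pos = as.character(tok$pos),
    head = if (is.null(tok$head)) NA_integer_ else as.integer(tok$head)
  )
}

#' Read a corpus from JSON Lines (+ optional metadata table)
#'
#' Malformed lines are rejected with their line number and the offending
#' field. Unknown pos tags are mapped to `"other"` with a single summary
#' warning. `call_index` is assigned per participant by date order.
#'
#' @param transcript_path JSON Lines transcript file (see [write_corpus()]).
#' @param meta_path Optional delimited metadata table (TSV or CSV by
#'   extension) with a header matching the participant metadata fields. When
#'   absent, a minimal participants table with `group = NA` is derived.
#' @return A validated `conv_corpus`.
#' @export
read_corpus <- function(transcript_path, meta_path = NULL) {
  lines <- readLines(transcript_path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  n_unknown_pos <- 0L
  convs <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop(sprintf("line %d: invalid JSON (%s)",
                                       i, conditionMessage(e)), call. = FALSE)
    )
    for (f in c("participant_id", "date", "sentences")) {
      if (is.null(obj[[f]])) {
        stop(sprintf("line %d: missing required field '%s'", i, f), call. = FALSE)
      }
    }
    sentences <- lapply(obj$sentences, function(sent) {
      toks <- lapply(sent, parse_token, line_no = i)
      pos <- vapply(toks, `[[`, character(1), "pos")
      unknown <- !pos %in% pos_tags()
      if (any(unknown)) {
        n_unknown_pos <<- n_unknown_pos + sum(unknown)
        pos[unknown] <- "other"
      }
      data.frame(
        surface = vapply(toks, `[[`, character(1), "surface"),
        lemma = vapply(toks, `[[`, character(1), "lemma"),
        pos = pos,
        head = vapply(toks, `[[`, integer(1), "head"),
        stringsAsFactors = FALSE
      )
    })
    convs[[length(convs) + 1L]] <- conversation(
      participant_id = obj$participant_id,
      date = obj$date,
      call_index = NA_integer_,
      sentences = sentences
    )
  }
  if (n_unknown_pos > 0L) {
    warning(sprintf("%d token(s) with unknown pos tag mapped to 'other'", n_unknown_pos),
            call. = FALSE)
  }
  # chronological call_index per participant
  pid <- vapply(convs, `[[`, character(1), "participant_id")
  dates <- as.Date(vapply(convs, function(cv) as.character(cv$date), character(1)))
  ord <- order(pid, dates)
  convs <- convs[ord]
  pid <- pid[ord]
  for (p in unique(pid)) {
    at <- which(pid == p)
    for (j in seq_along(at)) convs[[at[j]]]$call_index <- j
  }
  participants <- if (!is.null(meta_path)) {
    read_participants(meta_path)
  } else {
    tibble::tibble(participant_id = unique(pid), group = NA_character_)
  }
  conv_corpus(convs, participants)
}

read_participants <- function(meta_path) {
  reader <- if (grepl("\\.csv$", meta_path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  meta <- reader(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(meta)) {
    stop("metadata table missing required column 'participant_id'", call. = FALSE)
  }
  meta
}

#' Demographics of the monitoring-service participants
#'
#' Returns the packaged participant metadata table for the 15-person
#' longitudinal phone-call study the package's defaults are calibrated to:
#' 13 controls and 2 speakers with an Alzheimer disease diagnosis, with
#' follow-up duration, call counts, per-call minutes and per-call character
#' counts (mean and SD) per participant. Ages are stored as the printed
#' bands, not numbers.
#'
#' @return A tibble with 15 rows.
#' @export
load_demographics_fixture <- function() {
  path <- system.file("extdata", "table1_demographics.tsv", package = "convrep")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Summarize a participant metadata table
#'
#' Totals are sums over records; means are unweighted means over
#' participants, except `mean_chars_per_call`, which weights each
#' participant's per-call character mean by their call count (the per-call
#' average across the whole corpus). Both character-count summaries are
#' reported because they genuinely differ.
#'
#' @param meta Nonempty tibble of participant metadata.
#' @return A one-row tibble of summary values.
#' @export
corpus_summary <- function(meta) {
  if (is.null(meta) || nrow(meta) == 0L) stop("empty metadata table", call. = FALSE)
  out <- tibble::tibble(
    n_participants = nrow(meta),
    n_ad = sum(meta$group == "AD"),
    total_calls = sum(meta$n_calls),
    mean_calls = mean(meta$n_calls),
    mean_call_minutes = if ("mean_call_minutes" %in% names(meta)) {
      mean(meta$mean_call_minutes)
    } else NA_real_,
    mean_follow_up_months = if ("follow_up_months" %in% names(meta)) {
      mean(meta$follow_up_months)
    } else NA_real_
  )
  if ("mean_chars" %in% names(meta)) {
    out$mean_chars_by_participant <- mean(meta$mean_chars)
    out$mean_chars_per_call <- sum(meta$mean_chars * meta$n_calls) / sum(meta$n_calls)
    out$total_chars <- sum(meta$mean_chars * meta$n_calls)
  }
  out
}
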