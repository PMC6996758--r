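#' Exponential memory kernel for cross-day topic reuse
#'
#' The probability that a speaker reuses a topic from a conversation held
#' `s` days earlier is `r(s) = amplitude * exp(-s / decay_days)`. The
#' kernel must satisfy `r(s) <= 1` for all `s >= 1` and is monotone
#' decreasing by construction. A slowly decaying kernel models the
#' re-raising of recently discussed topics that persists over days.
#'
#' @param amplitude Nonnegative amplitude a (zero disables reuse).
#' @param decay_days Positive decay scale lambda, in days.
#' @return A `memory_kernel` list.
#' @export
memory_kernel <- function(amplitude, decay_days) {
  stopifnot(amplitude >= 0, decay_days > 0,
            amplitude * exp(-1 / decay_days) <= 1)
  structure(list(amplitude = amplitude, decay_days = decay_days),
            class = "memory_kernel")
}

#' Evaluate a memory kernel
#'
#' @param kernel A [memory_kernel()].
#' @param s Lag in days (vectorized).
#' @return Reuse probabilities.
#' @export
kernel_reuse_prob <- function(kernel, s) {
  kernel$amplitude * exp(-s / kernel$decay_days)
}

#' Integer lag maximizing the difference of two kernels
#'
#' `argmax_s r_a(s) - r_b(s)` over `s_range`; with the AD kernel as `a`
#' and the control kernel as `b` this is the lag at which the group
#' difference in cross-day reuse — and hence the discriminability of
#' day-interval pair features — is designed to peak.
#'
#' @param kernel_a,kernel_b [memory_kernel()]s.
#' @param s_range Integer lags to scan.
#' @return The maximizing lag (smallest on ties).
#' @export
kernel_difference_argmax <- function(kernel_a, kernel_b, s_range = 1:60) {
  diffs <- kernel_reuse_prob(kernel_a, s_range) - kernel_reuse_prob(kernel_b, s_range)
  s_range[which.max(diffs)]
}

#' Configuration of the synthetic conversation generator
#'
#' Scale defaults mirror the longitudinal monitoring-service corpus the
#' package is calibrated to: 15 participants of whom 2 have AD, one call
#' every 3-7 days over months of follow-up, and per-call text of roughly a
#' thousand characters. Group differences are expressed through the reuse
#' kernels, the within-call topic-repeat probabilities, the active
#' vocabulary fractions, and the pronoun-substitution / conjunction-
#' insertion rates.
#'
#' @param seed Integer RNG seed (mandatory; same seed, byte-identical
#'   corpus).
#' @param n_participants,n_ad Participant counts (`n_ad < n_participants`;
#'   AD participants are listed last).
#' @param n_calls Calls per participant; `NULL` derives the count from the
#'   follow-up range and call gaps.
#' @param follow_up_months Range (lo, hi) of follow-up months when
#'   `n_calls` is `NULL`.
#' @param call_gap_days Integer days between consecutive calls are drawn
#'   uniformly from this set.
#' @param sentences_per_call,sentences_dispersion Negative-binomial mean
#'   and size for the per-call sentence count (floored at 2).
#' @param tokens_per_sentence_mean Target mean tokens per sentence,
#'   realized through the number of clauses per sentence.
#' @param K_true Number of latent topics.
#' @param pool_sizes Named integer vector of per-tag vocabulary pool sizes
#'   (noun, verb, adjective, adverb, pronoun, auxiliary_verb, conjunction).
#' @param topic_word_conc Dirichlet concentration of each topic's
#'   distribution over its content pools (small = sharply topical words).
#' @param base_topic_conc_ctrl,base_topic_conc_ad Per-component Dirichlet
#'   parameter of a participant's base topic distribution (large =
#'   near-uniform). A small AD value narrows the personal topic repertoire
#'   — the recurrent-story-set phenomenon — which is what separates the
#'   groups at every pairing interval, while the kernels shape how the
#'   separation varies with the interval.
#' @param topic_drift_days Time scale, in days, on which a participant's
#'   base topic distribution drifts toward fresh draws (conversation content
#'   tracks life events); `Inf` disables drift. Drift applies to both groups;
#'   against it, the AD kernel's long memory re-raises old topics.
#' @param kernel_ctrl,kernel_ad [memory_kernel()]s per group.
#' @param p_within_ctrl,p_within_ad Probability that a sentence continues
#'   the current topic episode (repeats the previous sentence's topic);
#'   applies identically to fresh and reused topics, so episode structure
#'   is independent of the reuse mechanism.
#' @param active_vocab_frac_ctrl,active_vocab_frac_ad Fraction of each
#'   content pool the group actually uses (smaller = poorer vocabulary).
#' @param pronoun_sub_ctrl,pronoun_sub_ad Probability a noun slot is
#'   realized as a pronoun.
#' @param conj_insert_ctrl,conj_insert_ad Probability a sentence is opened
#'   with a conjunction.
#' @param assert_scale Assert at generation time that the corpus mean
#'   per-call character count lies in \[600, 1600\].
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_participants = 15L, n_ad = 2L,
                             n_calls = NULL,
                             follow_up_months = c(6, 33),
                             call_gap_days = 3:7,
                             sentences_per_call = 18, sentences_dispersion = 10,
                             tokens_per_sentence_mean = 10,
                             K_true = 60L,
                             pool_sizes = c(noun = 400L, verb = 250L, adjective = 120L,
                                            adverb = 80L, pronoun = 10L,
                                            auxiliary_verb = 10L, conjunction = 8L),
                             topic_word_conc = 0.05,
                             base_topic_conc_ctrl = 8, base_topic_conc_ad = 8,
                             topic_drift_days = Inf,
                             kernel_ctrl = memory_kernel(0.95, 3),
                             kernel_ad = memory_kernel(0.95, 3),
                             p_within_ctrl = 0.6, p_within_ad = 0.6,
                             active_vocab_frac_ctrl = 1.0, active_vocab_frac_ad = 1.0,
                             pronoun_sub_ctrl = 0.06, pronoun_sub_ad = 0.06,
                             conj_insert_ctrl = 0.06, conj_insert_ad = 0.06,
                             assert_scale = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' @param cfg A `generator_config` (possibly with fields modified).
#' @return The config invisibly re-classed, after invariant checks.
#' @export
validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_within_ctrl, cfg$p_within_ad,
             cfg$active_vocab_frac_ctrl, cfg$active_vocab_frac_ad,
             cfg$pronoun_sub_ctrl, cfg$pronoun_sub_ad,
             cfg$conj_insert_ctrl, cfg$conj_insert_ad)
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1L,
    cfg$n_ad < cfg$n_participants, cfg$n_participants >= 1L, cfg$n_ad >= 0L,
    all(probs >= 0 & probs <= 1),
    cfg$active_vocab_frac_ctrl > 0, cfg$active_vocab_frac_ad > 0,
    inherits(cfg$kernel_ctrl, "memory_kernel"),
    inherits(cfg$kernel_ad, "memory_kernel"),
    cfg$K_true >= 2L, cfg$topic_word_conc > 0,
    cfg$base_topic_conc_ctrl > 0, cfg$base_topic_conc_ad > 0,
    cfg$topic_drift_days > 0,
    all(cfg$pool_sizes >= 2L), all(cfg$call_gap_days >= 1L),
    is.null(cfg$n_calls) || cfg$n_calls >= 1L
  )
  invisible(structure(cfg, class = "generator_config"))
}

#' Named generator scenarios
#'
#' * `null`: both groups share every parameter — the no-effect calibration
#'   scenario (group labels are exchangeable by construction).
#' * `ad_effect`: the AD group re-raises topics across days (slowly decaying
#'   reuse kernel whose difference from the control kernel peaks at a 7-day
#'   lag) and cycles a narrowed personal topic repertoire, repeats within
#'   calls slightly more, uses a slightly smaller active vocabulary, and has
#'   elevated pronoun-substitution and conjunction-insertion rates. Topic
#'   repertoires drift over weeks for both groups, so cross-day similarity
#'   genuinely decays with the interval.
#' * `repetition_only`: only the reuse kernels differ — the specificity
#'   scenario in which part-of-speech features should show nothing.
#'
#' @param seed Seed stored in every returned config.
#' @return Named list of `generator_config`s.
#' @export
default_scenarios <- function(seed = 1L) {
  ctrl_kernel <- memory_kernel(1.3, 3.2)
  ad_kernel <- memory_kernel(0.95, 10)
  list(
    null = generator_config(seed = seed, n_ad = 2L),
    ad_effect = generator_config(
      seed = seed,
      K_true = 40L, topic_word_conc = 0.04,
      kernel_ctrl = ctrl_kernel, kernel_ad = ad_kernel,
      base_topic_conc_ad = 0.05, topic_drift_days = 12,
      p_within_ctrl = 0.60, p_within_ad = 0.61,
      active_vocab_frac_ctrl = 1.0, active_vocab_frac_ad = 0.95,
      pronoun_sub_ctrl = 0.06, pronoun_sub_ad = 0.065,
      conj_insert_ctrl = 0.06, conj_insert_ad = 0.065
    ),
    repetition_only = generator_config(
      seed = seed,
      K_true = 40L, topic_word_conc = 0.04,
      kernel_ctrl = ctrl_kernel, kernel_ad = ad_kernel,
      topic_drift_days = 12
    )
  )
}

# ---- internal building blocks -------------------------------------------

# sample from the *values* of x even when x has length 1
sample_vec <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

# fast data.frame constructor (no checks, no name repair)
fast_df <- function(surface, lemma, pos, head) {
  structure(list(surface = surface, lemma = lemma, pos = pos, head = head),
            class = "data.frame", row.names = seq_along(surface))
}

make_word_pool <- function(n) {
  lens <- sample(3:9, n, replace = TRUE)
  words <- vapply(lens, function(l) {
    paste(sample(letters, l, replace = TRUE), collapse = "")
  }, character(1))
  # regenerate any duplicates so lemmas are distinct types
  while (anyDuplicated(words) > 0L) {
    dup <- which(duplicated(words))
    words[dup] <- vapply(sample(3:9, length(dup), replace = TRUE), function(l) {
      paste(sample(letters, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  words
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# one verb per clause; every non-verb token attaches to its clause verb,
# each clause verb attaches to the next clause's verb, last verb is root
CLAUSE_PATTERNS <- list(
  c("noun", "verb"),
  c("noun", "noun", "verb"),
  c("adverb", "noun", "verb"),
  c("adjective", "noun", "verb"),
  c("noun", "verb", "auxiliary_verb"),
  c("noun", "adjective", "noun", "verb"),
  c("adverb", "noun", "noun", "verb", "auxiliary_verb")
)

compose_template <- function(n_clauses) {
  picks <- sample.int(length(CLAUSE_PATTERNS), n_clauses, replace = TRUE)
  pos <- character(0)
  heads <- integer(0)
  verb_global <- integer(n_clauses)
  offset <- 0L
  for (ci in seq_len(n_clauses)) {
    pat <- CLAUSE_PATTERNS[[picks[ci]]]
    v_local <- which(pat == "verb")
    verb_global[ci] <- offset + v_local - 1L  # 0-based
    h <- rep(verb_global[ci], length(pat))
    pos <- c(pos, pat)
    heads <- c(heads, h)
    offset <- offset + length(pat)
  }
  for (ci in seq_len(n_clauses)) {
    heads[verb_global[ci] + 1L] <-
      if (ci < n_clauses) verb_global[ci + 1L] else -1L
  }
  list(pos = pos, heads = heads)
}

#' Generate a synthetic longitudinal conversation corpus
#'
#' Per participant, a call schedule is laid out; per call, a sentence count
#' is drawn; per sentence, a topic is chosen by one of three mechanisms:
#' with probability `p_within` the previous sentence's topic is repeated
#' (topics therefore arrive in geometric episodes, for fresh and reused
#' topics alike); otherwise a past call is sampled with probability
#' proportional to the kernel at its lag (memory accessibility) and, with
#' the kernel probability `r(s)` at that lag `s` in days, one of that
#' call's topics is reused; otherwise a fresh topic is drawn from the
#' participant's base distribution. Tokens are then slotted into a clause-composed dependency
#' template: noun/verb/adjective slots draw from the chosen topic's word
#' distributions restricted to the group's active vocabulary, noun slots
#' may be realized as pronouns, and sentences may open with a conjunction.
#' Lemma equals surface (no morphology is simulated). Every topic choice
#' and reuse trial is recorded in the ground-truth table, so downstream
#' checks never need to re-infer latent structure.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a `conv_corpus`), `ground_truth` (a tibble
#'   with one row per sentence: mechanism, topic, reuse trial lag and
#'   outcome) and `config`.
#' @export
generate_corpus <- function(config) {
  config <- validate_generator_config(config)
  set.seed(config$seed)

  pools <- lapply(config$pool_sizes, make_word_pool)
  K <- config$K_true
  # topic-specific word distributions over the content pools
  content_tags <- c("noun", "verb", "adjective", "adverb")
  topic_dists <- lapply(content_tags, function(tag) {
    vapply(seq_len(K), function(k) {
      rdirichlet1(rep(config$topic_word_conc, config$pool_sizes[[tag]]))
    }, numeric(config$pool_sizes[[tag]]))
  })
  names(topic_dists) <- content_tags

  n_ctrl <- config$n_participants - config$n_ad
  ids <- c(sprintf("S%02d", seq_len(n_ctrl)),
           sprintf("A%02d", seq_len(config$n_ad)))
  groups <- c(rep("control", n_ctrl), rep("AD", config$n_ad))

  group_par <- function(g) {
    if (g == "AD") {
      list(kernel = config$kernel_ad, p_within = config$p_within_ad,
           active = config$active_vocab_frac_ad,
           pronoun_sub = config$pronoun_sub_ad,
           conj_insert = config$conj_insert_ad,
           base_conc = config$base_topic_conc_ad)
    } else {
      list(kernel = config$kernel_ctrl, p_within = config$p_within_ctrl,
           active = config$active_vocab_frac_ctrl,
           pronoun_sub = config$pronoun_sub_ctrl,
           conj_insert = config$conj_insert_ctrl,
           base_conc = config$base_topic_conc_ctrl)
    }
  }

  # topic dists restricted to each group's active vocabulary, renormalized
  restricted <- lapply(unique(groups), function(g) {
    f <- group_par(g)$active
    out <- lapply(names(topic_dists), function(tag) {
      n_active <- max(2L, ceiling(f * config$pool_sizes[[tag]]))
      d <- topic_dists[[tag]][seq_len(n_active), , drop = FALSE]
      sweep(d, 2L, colSums(d), "/")
    })
    names(out) <- names(topic_dists)
    out
  })
  names(restricted) <- unique(groups)

  clause_rate <- max(0, config$tokens_per_sentence_mean / 3.3 - 1)
  base_date <- as.Date("2019-01-07")

  convs <- list()
  gt_rows <- vector("list", 0L)
  meta_rows <- vector("list", 0L)

  for (pi in seq_along(ids)) {
    g <- groups[pi]
    par <- group_par(g)
    dists <- restricted[[g]]
    base_theta <- rdirichlet1(rep(par$base_conc, K))

    # schedule
    if (is.null(config$n_calls)) {
      months <- stats::runif(1, config$follow_up_months[1], config$follow_up_months[2])
      horizon <- months * 30.4
      days <- 0
      repeat {
        nxt <- days[length(days)] + sample_vec(config$call_gap_days, 1L)
        if (nxt > horizon) break
        days <- c(days, nxt)
      }
    } else {
      gaps <- sample_vec(config$call_gap_days, config$n_calls - 1L)
      days <- cumsum(c(0, gaps))
    }
    dates <- base_date + days
    n_calls <- length(dates)

    call_topics <- vector("list", n_calls)
    call_chars <- numeric(n_calls)
    p_convs <- vector("list", n_calls)

    for (ci in seq_len(n_calls)) {
      if (ci > 1L && is.finite(config$topic_drift_days)) {
        # the personal repertoire drifts between calls at the configured
        # time scale: each topic's mass moves to a fresh topic with the
        # gap-dependent probability, so overlap between two calls decays as
        # exp(-lag/drift) while the repertoire stays exactly as narrow;
        # reuse via the kernel re-raises topics against this drift
        p_swap <- 1 - exp(-as.numeric(dates[ci] - dates[ci - 1L]) /
                            config$topic_drift_days)
        moved <- stats::runif(K) < p_swap
        if (any(moved)) {
          dest <- sample.int(K, sum(moved), replace = TRUE)
          gain <- vapply(seq_len(K), function(k) {
            sum(base_theta[moved][dest == k])
          }, numeric(1))
          base_theta[moved] <- 0
          base_theta <- base_theta + gain
          base_theta <- base_theta / sum(base_theta)
        }
      }
      S <- max(1L, stats::rnbinom(1L, size = config$sentences_dispersion,
                                  mu = config$sentences_per_call))
      sentences <- vector("list", S)
      topics <- integer(S)
      mech <- character(S)
      lag <- rep(NA_integer_, S)
      attempt <- logical(S)
      reused <- logical(S)

      # a new episode never repeats the episode it directly follows (that
      # continuation is what p_within models), but may re-raise any earlier
      # topic of the call — a narrow repertoire is allowed to recur
      prev_topic <- 0L
      fresh_draw <- function() {
        open <- setdiff(seq_len(K), prev_topic)
        # tiny floor keeps zero-mass topics (possible after drift) drawable
        p <- base_theta[open] + 1e-9
        open[sample.int(length(open), 1L, prob = p)]
      }
      for (si in seq_len(S)) {
        # topics arrive in episodes: each sentence continues the current
        # episode with probability p_within, for fresh and reused topics
        # alike, so reuse changes only where topics come from, never the
        # run-length structure of a call
        if (si > 1L && stats::runif(1) < par$p_within) {
          topics[si] <- topics[si - 1L]
          mech[si] <- "within"
        } else if (ci > 1L) {
          # the source call is drawn by memory accessibility: weight past
          # calls by the kernel at their lag (uniform if all weights vanish)
          lags_all <- as.integer(dates[ci] - dates[seq_len(ci - 1L)])
          wts <- kernel_reuse_prob(par$kernel, lags_all)
          q <- if (sum(wts) > 0) {
            sample.int(ci - 1L, 1L, prob = wts)
          } else {
            sample.int(ci - 1L, 1L)
          }
          s_lag <- lags_all[q]
          attempt[si] <- TRUE
          lag[si] <- s_lag
          transplantable <- setdiff(call_topics[[q]], prev_topic)
          if (length(transplantable) > 0L &&
              stats::runif(1) < kernel_reuse_prob(par$kernel, s_lag)) {
            topics[si] <- sample_vec(transplantable, 1L)
            mech[si] <- "reuse"
            reused[si] <- TRUE
          } else {
            topics[si] <- fresh_draw()
            mech[si] <- "fresh"
          }
        } else {
          topics[si] <- fresh_draw()
          mech[si] <- "fresh"
        }
        prev_topic <- topics[si]

        tmpl <- compose_template(1L + stats::rpois(1L, clause_rate))
        pos <- tmpl$pos
        heads <- tmpl$heads
        k <- topics[si]
        words <- character(length(pos))
        for (tag in c("noun", "verb", "adjective", "adverb")) {
          at <- which(pos == tag)
          if (length(at) > 0L) {
            d <- dists[[tag]][, k]
            words[at] <- pools[[tag]][sample.int(length(d), length(at),
                                                 replace = TRUE, prob = d)]
          }
        }
        at <- which(pos == "auxiliary_verb")
        if (length(at) > 0L) {
          words[at] <- sample(pools[["auxiliary_verb"]], length(at), replace = TRUE)
        }
        noun_at <- which(pos == "noun")
        if (length(noun_at) > 0L && par$pronoun_sub > 0) {
          sub <- noun_at[stats::runif(length(noun_at)) < par$pronoun_sub]
          if (length(sub) > 0L) {
            words[sub] <- sample(pools[["pronoun"]], length(sub), replace = TRUE)
            pos[sub] <- "pronoun"
          }
        }
        if (stats::runif(1) < par$conj_insert) {
          root <- which(heads == -1L) - 1L  # 0-based root position
          heads <- c(root[1L] + 1L, heads + ifelse(heads == -1L, 0L, 1L))
          pos <- c("conjunction", pos)
          words <- c(sample(pools[["conjunction"]], 1L), words)
        }
        sentences[[si]] <- fast_df(words, words, pos, as.integer(heads))
      }

      call_topics[[ci]] <- topics
      call_chars[ci] <- sum(nchar(unlist(lapply(sentences, `[[`, "surface"),
                                         use.names = FALSE)))
      p_convs[[ci]] <- conversation(ids[pi], dates[ci], ci, sentences)
      gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
        participant_id = ids[pi], group = g, call_index = ci, date = dates[ci],
        sentence_index = seq_len(S), topic = topics, mechanism = mech,
        lag = lag, reuse_attempt = attempt, reused = reused
      )
    }

    convs <- c(convs, p_convs)
    meta_rows[[pi]] <- tibble::tibble(
      participant_id = ids[pi], group = g,
      sex = sample(c("F", "M"), 1L, prob = c(0.8, 0.2)),
      age_band = {
        a <- sample(61:88, 1L)
        paste0(a, "-", a + sample(0:3, 1L))
      },
      follow_up_months = round(as.numeric(dates[n_calls] - dates[1]) / 30.4, 1),
      n_calls = n_calls,
      mean_call_minutes = round(mean(call_chars) / 90, 1),
      mean_chars = round(mean(call_chars), 1)
    )
  }

  meta <- dplyr::bind_rows(meta_rows)
  corpus <- conv_corpus(convs, meta)
  if (isTRUE(config$assert_scale)) {
    mean_chars <- sum(meta$mean_chars * meta$n_calls) / sum(meta$n_calls)
    if (mean_chars < 600 || mean_chars > 1600) {
      stop(sprintf("generated corpus mean per-call character count %.0f outside [600, 1600]",
                   mean_chars), call. = FALSE)
    }
  }
  list(corpus = corpus, ground_truth = dplyr::bind_rows(gt_rows), config = config)
}

#' Empirical cross-day reuse rate from generator ground truth
#'
#' Reuse events over reuse opportunities (sentences whose topic mechanism
#' ran a kernel trial) per lag bin; compare with [kernel_reuse_prob()] at
#' the configured kernel.
#'
#' @param ground_truth The `ground_truth` tibble from [generate_corpus()].
#' @param lags Integer lags (bin centers) to report.
#' @param tol_days Pool lags within `tol_days` of each center (default 0,
#'   exact-lag bins).
#' @param group Optional group filter (`"control"` or `"AD"`).
#' @return Tibble (lag, n_opportunities, n_reused, rate); empty bins are
#'   reported with `NA` rate and a warning.
#' @export
measured_reuse_rate <- function(ground_truth, lags, tol_days = 0L, group = NULL) {
  gt <- ground_truth[ground_truth$reuse_attempt, , drop = FALSE]
  if (!is.null(group)) gt <- gt[gt$group == group, , drop = FALSE]
  rows <- lapply(lags, function(s) {
    sel <- abs(gt$lag - s) <= tol_days
    n <- sum(sel)
    tibble::tibble(
      lag = s, n_opportunities = n, n_reused = sum(gt$reused[sel]),
      rate = if (n == 0L) NA_real_ else sum(gt$reused[sel]) / n
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$n_opportunities == 0L)) {
    warning("empty lag bin(s): ",
            paste(out$lag[out$n_opportunities == 0L], collapse = ", "),
            call. = FALSE)
  }
  out
}
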