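#' Interval window for conversation pairing
#'
#' Admits pairs whose separation x (days or calls by `mode`) satisfies the
#' half-open rule `center - half_width < x <= center + half_width`.
#'
#' @param center Positive integer (the T of a day interval or N of a call
#'   interval).
#' @param half_width Positive integer M (analysis default 3).
#' @param mode `"days"` or `"calls"`.
#' @return An `interval_window` list.
#' @export
interval_window <- function(center, half_width = 3L, mode = c("days", "calls")) {
  mode <- match.arg(mode)
  center <- as.integer(center); half_width <- as.integer(half_width)
  stopifnot(center >= 1L, half_width >= 1L, center - half_width >= 0L)
  structure(list(center = center, half_width = half_width, mode = mode),
            class = "interval_window")
}

#' Packaged default interval windows
#'
#' The selected centers for each feature family: day interval T = 10 and
#' call interval N = 7 for word repetition; T = 7 and N = 9 for topic
#' repetition; half-width M = 3 throughout.
#'
#' @return Named list of four [interval_window()]s.
#' @export
default_interval_windows <- function() {
  list(
    word_days = interval_window(10L, 3L, "days"),
    word_calls = interval_window(7L, 3L, "calls"),
    topic_days = interval_window(7L, 3L, "days"),
    topic_calls = interval_window(9L, 3L, "calls")
  )
}

#' Build all admissible conversation pairs
#'
#' For every participant, every chronologically ordered pair of that
#' participant's conversations whose interval falls in the window is
#' returned; pairs never cross participants. Output ordering is
#' deterministic (participant, earlier date, later date) regardless of
#' input order.
#'
#' @param corpus A `conv_corpus`.
#' @param window An [interval_window()].
#' @return Tibble with columns `participant_id`, `earlier`, `later`
#'   (indices into `corpus$conversations`), `earlier_date`, `later_date`,
#'   `delta_days`, `delta_calls` (possibly zero rows).
#' @export
build_pairs <- function(corpus, window) {
  stopifnot(inherits(window, "interval_window"))
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  pid <- vapply(corpus$conversations, `[[`, character(1), "participant_id")
  dates <- as.Date(vapply(corpus$conversations, function(cv) as.character(cv$date),
                          character(1)))
  idx <- vapply(corpus$conversations, `[[`, integer(1), "call_index")
  rows <- list()
  for (p in sort(unique(pid))) {
    at <- which(pid == p)
    at <- at[order(dates[at])]
    n <- length(at)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        dd <- as.integer(dates[at[j]] - dates[at[i]])
        dc <- idx[at[j]] - idx[at[i]]
        x <- if (window$mode == "days") dd else dc
        if (x > lo && x <= hi) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant_id = p,
            earlier = at[i], later = at[j],
            earlier_date = dates[at[i]], later_date = dates[at[j]],
            delta_days = dd, delta_calls = dc
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      participant_id = character(0), earlier = integer(0), later = integer(0),
      earlier_date = as.Date(character(0)), later_date = as.Date(character(0)),
      delta_days = integer(0), delta_calls = integer(0)
    ))
  }
  dplyr::bind_rows(rows)
}

pair_groups <- function(corpus, pairs) {
  corpus$participants$group[match(pairs$participant_id,
                                  corpus$participants$participant_id)]
}

#' Grid search over the interval center
#'
#' For each candidate center, builds the pairs, evaluates the pair feature,
#' and scores its discrimination of AD from control pairs by AUC-ROC (the
#' selection metric the discriminative-power curves are plotted in; Cohen's
#' |d| is available via `objective = "effect_size"`). Candidates whose
#' pairs cover only one group are excluded with a warning. Ties go to the
#' smallest center.
#'
#' @param corpus A `conv_corpus` whose participants table has `group`.
#' @param feature_fn `function(earlier_conv, later_conv)` returning one
#'   numeric pair-feature value.
#' @param candidates Nonempty integer vector of centers.
#' @param half_width Window half-width M.
#' @param mode `"days"` or `"calls"`.
#' @param objective `"auc"` (default) or `"effect_size"`.
#' @return List with `best_center` and `curve`, a tibble
#'   (center, n_pairs_control, n_pairs_ad, auc, abs_d).
#' @export
grid_search_interval <- function(corpus, feature_fn, candidates,
                                 half_width = 3L, mode = c("days", "calls"),
                                 objective = c("auc", "effect_size")) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  stopifnot(length(candidates) >= 1L)
  rows <- lapply(sort(unique(as.integer(candidates))), function(center) {
    pairs <- build_pairs(corpus, interval_window(center, half_width, mode))
    grp <- pair_groups(corpus, pairs)
    vals <- vapply(seq_len(nrow(pairs)), function(r) {
      as.numeric(feature_fn(corpus$conversations[[pairs$earlier[r]]],
                            corpus$conversations[[pairs$later[r]]]))
    }, numeric(1))
    ok <- !is.na(vals) & !is.na(grp)
    vals <- vals[ok]; grp <- grp[ok]
    if (sum(grp == "control") < 2L || sum(grp == "AD") < 2L) {
      warning(sprintf("center %d: fewer than two pairs in some group; excluded",
                      center), call. = FALSE)
      return(NULL)
    }
    d <- cohens_d_ci(vals[grp == "control"], vals[grp == "AD"])
    tibble::tibble(
      center = center,
      n_pairs_control = sum(grp == "control"),
      n_pairs_ad = sum(grp == "AD"),
      auc = auc_roc(vals, grp),
      abs_d = abs(d$d)
    )
  })
  curve <- dplyr::bind_rows(rows)
  if (nrow(curve) == 0L) stop("no candidate produced pairs from both groups", call. = FALSE)
  score <- if (objective == "auc") curve$auc else curve$abs_d
  best <- curve$center[which.max(score)]  # which.max takes the first (smallest center) on ties
  list(best_center = best, curve = curve)
}
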