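#' Two-sided two-sample Student t test
#'
#' Equal-variance (pooled) Student t, as opposed to Welch; `welch = TRUE`
#' switches. Degenerate input (zero pooled variance) is flagged with `NA`
#' statistics rather than an error.
#'
#' @param x,y Numeric samples with at least two values each.
#' @param welch Use the Welch unequal-variance form.
#' @return List with `statistic`, `df`, `p_value`, `flagged`.
#' @export
student_t_two_sided <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  res <- tryCatch(
    stats::t.test(x, y, var.equal = !welch, alternative = "two.sided"),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                flagged = TRUE))
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, flagged = FALSE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`; the family size defaults to the batch length
#' but is configurable since feature batches of different sizes are
#' compared.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param m Family size (default `length(p_values)`).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1L)
  stats::p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Cohen's d with a 95% confidence interval
#'
#' `d = (mean(x) - mean(y)) / s_pooled`. With x = control and y = AD,
#' increased repetition in the AD group gives negative d. The CI uses the
#' normal-approximation standard error
#' `SE = sqrt((n_x + n_y)/(n_x n_y) + d^2 / (2 (n_x + n_y)))`.
#'
#' @param x,y Numeric samples (x = control, y = AD by convention).
#' @return List with `d`, `ci_low`, `ci_high`, `flagged`.
#' @export
cohens_d_ci <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) {
    return(list(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_, flagged = TRUE))
  }
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((nx + ny) / (nx * ny) + d^2 / (2 * (nx + ny)))
  list(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se, flagged = FALSE)
}

#' AUC-ROC by the Mann-Whitney formulation
#'
#' The probability that a randomly chosen positive-class (AD) sample
#' scores above a randomly chosen control sample, with ties counted half.
#' The value is reported in the orientation that treats the feature as an
#' AD score: an anti-predictive feature gives AUC < 0.5, with no
#' `max(a, 1 - a)` folding.
#'
#' @param scores Numeric feature values.
#' @param labels Group labels parallel to `scores`.
#' @param positive The positive class label (default `"AD"`).
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels, positive = "AD") {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank features by discriminative power
#'
#' Takes long-format per-sample feature values, computes one group
#' comparison per feature (AUC-ROC, Cohen's d with 95% CI, raw and
#' Bonferroni-adjusted two-sided Student t p values, sample sizes), and
#' ranks by AUC descending with ties broken by |d| descending then feature
#' name. Features whose samples do not admit a comparison (one group
#' empty after NA removal, or zero variance) are returned in the
#' `skipped` attribute. Each conversation (single features) or pair (pair
#' features) is one labeled sample; pairs from one participant are not
#' independent, so the per-unit n is reported and should be read with that
#' caveat.
#'
#' @param samples Tibble with columns `feature`, `value`, `group` and
#'   optionally `unit`.
#' @param m Bonferroni family size (default: number of distinct features).
#' @param alpha Adjusted-p significance rule (default 0.01).
#' @param welch Use Welch's t instead of pooled Student t.
#' @return Tibble of ranked comparisons with a `skipped` attribute; also
#'   reports `auc_folded = max(auc, 1 - auc)` for side-by-side reading
#'   with oriented AUC.
#' @export
rank_features <- function(samples, m = NULL, alpha = 0.01, welch = FALSE) {
  stopifnot(all(c("feature", "value", "group") %in% names(samples)))
  feats <- unique(samples$feature)
  if (is.null(m)) m <- length(feats)
  rows <- list(); skipped <- character(0)
  for (f in feats) {
    # non-finite values (e.g. the infinite-HS sentinel) are flagged missing
    sub <- samples[samples$feature == f & is.finite(samples$value), , drop = FALSE]
    x <- sub$value[sub$group == "control"]
    y <- sub$value[sub$group == "AD"]
    if (length(x) < 2L || length(y) < 2L) {
      skipped <- c(skipped, f)
      next
    }
    tt <- student_t_two_sided(x, y, welch = welch)
    dd <- cohens_d_ci(x, y)
    if (tt$flagged || dd$flagged) {
      skipped <- c(skipped, f)
      next
    }
    au <- auc_roc(sub$value, sub$group)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = f,
      unit = if ("unit" %in% names(sub)) sub$unit[1] else NA_character_,
      auc = au, auc_folded = max(au, 1 - au),
      d = dd$d, d_ci_low = dd$ci_low, d_ci_high = dd$ci_high,
      p_raw = tt$p_value,
      n_control = length(x), n_ad = length(y)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no feature with valid samples in both groups", call. = FALSE)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, m = m)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(-out$auc, -abs(out$d), out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  attr(out, "skipped") <- skipped
  attr(out, "m_bonferroni") <- m
  out
}

#' Packaged reference significance patterns
#'
#' The expected significance (sig / nonsig) of 24 standard linguistic
#' features in prior group-comparison studies of connected speech during
#' neuropsychological testing, transcribed for consistency checking
#' against this package's own comparisons.
#'
#' @return Tibble with columns `feature`, `category`, `previous_studies`.
#' @export
load_reference_patterns <- function() {
  path <- system.file("extdata", "reference_patterns.tsv", package = "convrep")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Consistency of significance patterns against a reference
#'
#' Classifies each feature shared between `comparisons` and the reference
#' as sig-sig, nonsig-nonsig (consistent), or sig-nonsig, nonsig-sig
#' (inconsistent), using the adjusted-p < `alpha` rule on our side.
#' Features absent from the reference are listed separately.
#'
#' @param comparisons Output of [rank_features()].
#' @param reference Tibble with columns `feature` and `previous_studies`
#'   (values `"sig"`/`"nonsig"`); default the packaged reference.
#' @param alpha Significance rule for our comparisons.
#' @return List with `table` (feature, ours, previous, pattern,
#'   consistent), `counts` (named pattern counts), `unmatched_ours`,
#'   `unmatched_reference`.
#' @export
significance_pattern_report <- function(comparisons,
                                        reference = load_reference_patterns(),
                                        alpha = 0.01) {
  stopifnot(all(c("feature", "previous_studies") %in% names(reference)))
  shared <- intersect(comparisons$feature, reference$feature)
  ours <- ifelse(comparisons$p_adjusted[match(shared, comparisons$feature)] < alpha,
                 "sig", "nonsig")
  prev <- reference$previous_studies[match(shared, reference$feature)]
  pattern <- paste(ours, prev, sep = "-")
  tab <- tibble::tibble(
    feature = shared, ours = ours, previous = prev, pattern = pattern,
    consistent = ours == prev
  )
  counts <- vapply(c("sig-sig", "nonsig-nonsig", "sig-nonsig", "nonsig-sig"),
                   function(p) sum(pattern == p), integer(1))
  list(
    table = tab,
    counts = counts,
    unmatched_ours = setdiff(comparisons$feature, reference$feature),
    unmatched_reference = setdiff(reference$feature, comparisons$feature)
  )
}
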