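small_gen_config <- function(seed, ...) {
  args <- list(seed = seed, n_participants = 4L, n_ad = 2L, n_calls = 6L,
               assert_scale = FALSE)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

test_that("memory kernels respect their invariants", {
  k <- memory_kernel(0.8, 3)
  s <- 1:30
  r <- kernel_reuse_prob(k, s)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(diff(r) < 0))
  expect_error(memory_kernel(-0.1, 3))
  expect_error(memory_kernel(2, 100))  # r(1) would exceed 1
  expect_equal(kernel_reuse_prob(memory_kernel(0, 5), s), rep(0, 30))
})

test_that("the same seed yields a byte-identical corpus and ground truth", {
  cfg <- small_gen_config(123)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$conversations, g2$corpus$conversations)
  expect_identical(as.data.frame(g1$ground_truth), as.data.frame(g2$ground_truth))
  expect_identical(as.data.frame(g1$corpus$participants),
                   as.data.frame(g2$corpus$participants))
  g3 <- generate_corpus(small_gen_config(124))
  expect_false(identical(g1$corpus$conversations, g3$corpus$conversations))
})

test_that("a minimal configuration yields one well-formed conversation", {
  cfg <- generator_config(seed = 5, n_participants = 1L, n_ad = 0L, n_calls = 1L,
                          sentences_per_call = 1, assert_scale = FALSE)
  gen <- generate_corpus(cfg)
  expect_length(gen$corpus$conversations, 1L)
  conv <- gen$corpus$conversations[[1]]
  expect_gte(length(conv$sentences), 1L)
  s <- conv$sentences[[1]]
  expect_true(all(s$pos %in% pos_tags()))
  expect_equal(sum(s$head == -1L), 1L)  # exactly one dependency root
  expect_identical(s$surface, s$lemma)
  # generated corpora pass the full invariant checker by construction
  expect_true(validate_corpus(gen$corpus))
})

test_that("generated text lands at the realistic per-call character scale", {
  cfg <- generator_config(seed = 42, n_participants = 6L, n_ad = 2L, n_calls = 10L)
  gen <- generate_corpus(cfg)
  meta <- gen$corpus$participants
  mean_chars <- sum(meta$mean_chars * meta$n_calls) / sum(meta$n_calls)
  expect_gte(mean_chars, 600)
  expect_lte(mean_chars, 1600)
  expect_equal(meta$n_calls, rep(10L, 6))
})

test_that("ground truth records every topic decision", {
  gen <- generate_corpus(small_gen_config(7))
  gt <- gen$ground_truth
  n_sent <- sum(vapply(gen$corpus$conversations, function(cv) length(cv$sentences),
                       integer(1)))
  expect_equal(nrow(gt), n_sent)
  expect_true(all(gt$mechanism %in% c("fresh", "within", "reuse", "reuse_run")))
  expect_true(all(gt$reuse_attempt[gt$mechanism == "reuse"]))
  expect_true(all(!is.na(gt$lag[gt$reuse_attempt])))
  # first calls can never attempt reuse
  expect_true(all(!gt$reuse_attempt[gt$call_index == 1L]))
})

test_that("measured reuse rates handle trivial and empty bins", {
  gt <- tibble::tibble(
    participant_id = "S01", group = "control", call_index = 2L,
    date = as.Date("2020-01-08"), sentence_index = 1:4, topic = 1L,
    mechanism = c("reuse", "fresh", "fresh", "fresh"),
    lag = c(7L, 7L, 7L, 7L), reuse_attempt = TRUE,
    reused = c(TRUE, FALSE, FALSE, FALSE)
  )
  out <- measured_reuse_rate(gt, lags = 7L)
  expect_equal(out$rate, 0.25)
  expect_equal(out$n_opportunities, 4L)
  expect_warning(empty <- measured_reuse_rate(gt, lags = 3L), "empty")
  expect_true(is.na(empty$rate))
})

test_that("a zero-amplitude kernel produces no reuse anywhere", {
  cfg <- small_gen_config(9, kernel_ctrl = memory_kernel(0, 5),
                          kernel_ad = memory_kernel(0, 5), n_calls = 8L)
  gen <- generate_corpus(cfg)
  rates <- suppressWarnings(measured_reuse_rate(gen$ground_truth, lags = 3:10))
  expect_true(all(rates$rate[!is.na(rates$rate)] == 0))
})

test_that("empirical reuse rates agree with the configured kernel", {
  # daily calls and no within-call repetition give dense, clean lag bins
  kern <- memory_kernel(0.3, 10)
  cfg <- generator_config(seed = 77, n_participants = 40L, n_ad = 0L,
                          n_calls = 40L, call_gap_days = 1L,
                          sentences_per_call = 14,
                          p_within_ctrl = 0, kernel_ctrl = kern,
                          assert_scale = FALSE)
  gen <- generate_corpus(cfg)
  rates <- measured_reuse_rate(gen$ground_truth, lags = c(3L, 7L, 14L), tol_days = 1L)
  expect_true(all(rates$n_opportunities >= 500L))
  expect_true(all(abs(rates$rate - kernel_reuse_prob(kern, rates$lag)) <= 0.03))
})

test_that("scenario configurations are valid and structured as designed", {
  scen <- default_scenarios(seed = 3)
  expect_named(scen, c("null", "ad_effect", "repetition_only"))
  for (cfg in scen) expect_s3_class(validate_generator_config(cfg), "generator_config")
  # null: groups identical pointwise
  with(scen$null, {
    expect_identical(kernel_ctrl, kernel_ad)
    expect_identical(p_within_ctrl, p_within_ad)
    expect_identical(active_vocab_frac_ctrl, active_vocab_frac_ad)
  })
  # ad_effect: kernel-difference argmax in the designed band
  am <- kernel_difference_argmax(scen$ad_effect$kernel_ad, scen$ad_effect$kernel_ctrl)
  expect_true(am %in% 5:9)
  # repetition_only differs from null in kernels only
  ro <- scen$repetition_only
  expect_false(identical(ro$kernel_ctrl, ro$kernel_ad))
  expect_identical(ro$p_within_ctrl, ro$p_within_ad)
  expect_identical(ro$pronoun_sub_ctrl, ro$pronoun_sub_ad)
  expect_identical(ro$active_vocab_frac_ctrl, ro$active_vocab_frac_ad)
})

test_that("kernel-only group differences leave pos features silent", {
  scen <- default_scenarios(seed = 19)
  cfg <- scen$repetition_only
  cfg$n_participants <- 10L; cfg$n_ad <- 5L; cfg$n_calls <- 12L
  cfg <- validate_generator_config(cfg)
  gen <- generate_corpus(cfg)
  corp <- preprocess_corpus(gen$corpus, quiet = TRUE)
  groups <- corp$participants$group[match(
    vapply(corp$conversations, `[[`, character(1), "participant_id"),
    corp$participants$participant_id)]
  rows <- lapply(seq_along(corp$conversations), function(i) {
    vals <- pos_features(corp$conversations[[i]])
    tibble::tibble(feature = names(vals), value = unname(vals), group = groups[i])
  })
  rk <- rank_features(dplyr::bind_rows(rows))
  expect_false(any(rk$significant))
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(seed = 1, n_ad = 5L, n_participants = 5L))
  expect_error(generator_config(seed = 1, p_within_ctrl = 1.4))
  expect_error(generator_config(seed = 1, topic_drift_days = -2))
  expect_error(generator_config(seed = 1, base_topic_conc_ad = 0))
  expect_error(generator_config())  # seed mandatory
})

test_that("day-matched topic repetition rises with the reuse amplitude", {
  amplitudes <- c(0.05, 0.3, 0.55, 0.8, 0.95)
  mean_rep <- vapply(amplitudes, function(a) {
    kern <- memory_kernel(a, 10)
    cfg <- generator_config(seed = 201, n_participants = 10L, n_ad = 2L,
                            n_calls = 20L,
                            kernel_ctrl = kern, kernel_ad = kern,
                            assert_scale = FALSE)
    gen <- generate_corpus(cfg)
    corp <- preprocess_corpus(gen$corpus, quiet = TRUE)
    vocab <- build_vocab(corp)
    model <- fit_btm(build_training_set(corp, vocab),
                     btm_config(K = 40L, n_iterations = 120L, burn_in = 60L,
                                seed = 202L), vocab)
    rc <- repetition_config()
    wins <- lapply(corp$conversations, conversation_topic_windows,
                   model = model, l = rc$l)
    pairs <- build_pairs(corp, interval_window(7L, 3L, "days"))
    vals <- vapply(seq_len(nrow(pairs)), function(r) {
      as.numeric(topic_repetition_pair(NULL, NULL, model, rc,
                                       windows_a = wins[[pairs$earlier[r]]],
                                       windows_b = wins[[pairs$later[r]]]))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(cor(amplitudes, mean_rep, method = "spearman"), 0.9)
})
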