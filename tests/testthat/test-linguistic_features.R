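test_that("the registry exposes exactly the 29 standard features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 29L)
  expect_equal(as.integer(table(reg$category)[c("pos", "vocabulary_richness",
                                                "syntactic", "perseveration")]),
               c(14L, 3L, 7L, 5L))
  expect_false(anyDuplicated(reg$feature) > 0)
})

test_that("pos features follow their definitions on forced cases", {
  all_nouns <- conv_fix(list(noun_sent(letters[1:5])))
  pf <- pos_features(all_nouns)
  expect_equal(pf[["noun_frequency"]], 5)
  expect_equal(pf[["noun_ratio"]], 1)
  expect_equal(pf[["pronoun_ratio"]], 0)
  expect_true(is.na(pf[["noun_to_verb_ratio"]]))  # zero verbs flagged, not zero

  nv <- conv_fix(list(sent(c("a", "b", "c"), c("noun", "noun", "verb"))))
  expect_equal(pos_features(nv)[["noun_to_verb_ratio"]], 2)
})

test_that("pos ratios equal a brute-force tally on random streams", {
  set.seed(3)
  for (i in 1:30) {
    conv <- conv_fix(lapply(1:3, function(s) random_sentence(sample(2:8, 1),
                                                            analyzed_only = TRUE)))
    pf <- pos_features(conv)
    pos <- unlist(lapply(conv$sentences_filtered, `[[`, "pos"))
    V <- length(pos)
    for (tag in c("noun", "verb", "adjective", "pronoun", "adverb",
                  "auxiliary_verb", "conjunction")) {
      n_tag <- sum(pos == tag)
      expect_equal(pf[[paste0(tag, "_ratio")]], n_tag / V)
    }
    expect_equal(pf[["pronoun_to_noun_ratio"]],
                 if (sum(pos == "noun") == 0) NA_real_ else
                   sum(pos == "pronoun") / sum(pos == "noun"))
  }
})

test_that("vocabulary richness matches the closed formulas", {
  # V=100, U=50, V_uni=25: direct evaluation of the printed formulas
  vr <- vocabulary_richness(list(V = 100, U = 50, V_uni = 25))
  expect_equal(vr[["honore_statistic"]], 921.034, tolerance = 1e-6)
  expect_equal(vr[["honore_statistic"]], 100 * log(100) / (1 - 25 / 50))
  expect_equal(vr[["brunet_index"]], 100^(50^-0.165), tolerance = 1e-12)
  expect_equal(vr[["type_token_ratio"]], 0.5)
  # all-distinct boundary: TTR 1, HS infinite sentinel
  vr2 <- vocabulary_richness(list(V = 10, U = 10, V_uni = 10))
  expect_equal(vr2[["type_token_ratio"]], 1)
  expect_true(is.infinite(vr2[["honore_statistic"]]))
  expect_true(all(is.na(vocabulary_richness(list(V = 1, U = 1, V_uni = 1)))))
})

test_that("BI falls as types rise at fixed V; HS falls with fewer hapax", {
  bi <- vapply(c(20, 35, 50, 80), function(U) {
    vocabulary_richness(list(V = 100, U = U, V_uni = 10))[["brunet_index"]]
  }, numeric(1))
  expect_true(all(diff(bi) < 0))  # richer vocabulary, smaller BI
  hs <- vapply(c(40, 30, 20, 10), function(vu) {
    vocabulary_richness(list(V = 100, U = 50, V_uni = vu))[["honore_statistic"]]
  }, numeric(1))
  expect_true(all(diff(hs) < 0))  # more repetition, smaller HS
})

test_that("length metrics and dependency chains follow their definitions", {
  conv <- conv_fix(list(
    sent(c("a", "b", "c"), c("noun", "noun", "verb"), heads = c(2L, 2L, -1L)),
    sent(letters[4:8], rep("noun", 5), heads = c(-1L, 0L, 1L, 2L, 3L))
  ))
  sf <- syntactic_features(conv)
  expect_equal(sf[["mean_sentence_length"]], 4)
  expect_equal(sf[["sentence_count"]], 2)
  expect_equal(sf[["word_count"]], 8)
  expect_equal(sf[["character_count"]], 8)
  # chain a<-b<-c: two dependencies of distance 1 each
  chain <- conv_fix(list(sent(c("a", "b", "c"), c("noun", "noun", "verb"),
                              heads = c(-1L, 0L, 1L))))
  cf <- syntactic_features(chain)
  expect_equal(cf[["dependency_count"]], 2)
  expect_equal(cf[["total_dependency_distance"]], 2)
  expect_equal(cf[["avg_dependency_distance_per_sentence"]], 2)
  expect_equal(cf[["avg_dependencies_per_sentence"]], 2)
})

test_that("dependency distance equals a brute-force head re-walk on random trees", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(2:9, 1)
    # random tree: token j heads to some earlier token, token 1 is root
    heads <- c(-1L, vapply(2:n, function(j) sample(0:(j - 2), 1L), integer(1)))
    conv <- conv_fix(list(sent(sprintf("t%d", 1:n), rep("noun", n), heads = heads)))
    sf <- syntactic_features(conv)
    count <- 0L; dist <- 0L
    for (j in seq_len(n)) {
      h <- heads[j]
      if (h != -1L) {
        count <- count + 1L
        dist <- dist + abs((j - 1L) - h)
      }
    }
    expect_equal(sf[["dependency_count"]], count)
    expect_equal(sf[["total_dependency_distance"]], dist)
  }
})

test_that("dependency features are flagged missing without head annotation", {
  conv <- conv_fix(list(noun_sent(c("a", "b"))))
  sf <- syntactic_features(conv)
  expect_true(is.na(sf[["dependency_count"]]))
  expect_true(is.na(sf[["total_dependency_distance"]]))
  expect_false(is.na(sf[["word_count"]]))
})

test_that("perseveration statistics behave on forced sentence pairs", {
  twin <- conv_fix(list(noun_sent(c("a", "b")), noun_sent(c("a", "b"))))
  pv <- perseveration_features(twin)
  expect_equal(pv[["perseveration_min_dist"]], 0, tolerance = 1e-12)
  expect_equal(pv[["perseveration_mean_dist"]], 0, tolerance = 1e-12)
  expect_equal(pv[["perseveration_prop_dist_lt_030"]], 1)
  expect_equal(pv[["perseveration_prop_dist_lt_050"]], 1)
  expect_equal(pv[["perseveration_prop_sim_zero"]], 0)

  disjoint <- conv_fix(list(noun_sent(c("a", "b")), noun_sent(c("c", "d"))))
  pd <- perseveration_features(disjoint)
  expect_equal(pd[["perseveration_prop_sim_zero"]], 1)
  expect_equal(pd[["perseveration_min_dist"]], 1)

  single <- conv_fix(list(noun_sent(c("a", "b"))))
  expect_true(all(is.na(perseveration_features(single))))
})

test_that("perseveration matches an independent TF-IDF double loop", {
  set.seed(29)
  for (rep in 1:10) {
    conv <- conv_fix(lapply(1:5, function(s) {
      noun_sent(sample(sprintf("w%d", 1:8), sample(2:6, 1), replace = TRUE))
    }))
    got <- perseveration_features(conv)

    # independent implementation: explicit loops, same smoothed-idf convention
    sents <- lapply(conv$sentences_filtered, `[[`, "lemma")
    vocab <- unique(unlist(sents))
    S <- length(sents)
    vecs <- lapply(sents, function(lem) {
      tf <- vapply(vocab, function(w) sum(lem == w), numeric(1))
      df <- vapply(vocab, function(w) sum(vapply(sents, function(x) w %in% x, logical(1))),
                   numeric(1))
      tf * (log(S / df) + 1)
    })
    sims <- c(); dists <- c()
    for (i in 1:(S - 1)) for (j in (i + 1):S) {
      a <- vecs[[i]]; b <- vecs[[j]]
      cs <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      sims <- c(sims, cs); dists <- c(dists, 1 - cs)
    }
    expect_equal(got[["perseveration_prop_sim_zero"]], mean(sims == 0))
    expect_equal(got[["perseveration_prop_dist_lt_030"]], mean(dists < 0.3))
    expect_equal(got[["perseveration_prop_dist_lt_050"]], mean(dists < 0.5))
    expect_equal(got[["perseveration_min_dist"]], min(dists))
    expect_equal(got[["perseveration_mean_dist"]], mean(dists))
    expect_lte(got[["perseveration_min_dist"]], got[["perseveration_mean_dist"]])
  }
})

test_that("the similarity-threshold orientation is available by switch", {
  conv <- conv_fix(list(noun_sent(c("a", "b")), noun_sent(c("a", "c"))))
  d <- perseveration_features(conv, threshold_on = "distance")
  s <- perseveration_features(conv, threshold_on = "similarity")
  expect_equal(d[["perseveration_prop_dist_lt_050"]] + s[["perseveration_prop_dist_lt_050"]],
               1)
})

test_that("standard_features assembles the full registry vector", {
  conv <- conv_fix(list(
    sent(c("a", "b", "c"), c("noun", "noun", "verb"), heads = c(2L, 2L, -1L)),
    sent(c("a", "d", "e"), c("noun", "verb", "adverb"), heads = c(1L, -1L, 1L))
  ))
  sf <- standard_features(conv)
  expect_named(sf, feature_registry()$feature)
  expect_false(any(is.na(sf)))
})

test_that("TTR strictly decreases when a duplicate token is appended", {
  base <- letters[1:6]
  v1 <- vocabulary_richness(list(V = 6, U = 6, V_uni = 6))[["type_token_ratio"]]
  tab <- table(c(base, "a"))
  v2 <- vocabulary_richness(list(V = 7, U = length(tab),
                                 V_uni = sum(tab == 1)))[["type_token_ratio"]]
  expect_lt(v2, v1)
})
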