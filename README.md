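# convrep

People developing Alzheimer disease (AD) retell the same stories and reuse
the same words — within a conversation and, more tellingly, across
conversations held days apart. `convrep` measures this in longitudinal
conversation transcripts and asks which linguistic features best separate
AD speakers from controls. It is aimed at researchers working on speech- and
language-based digital biomarkers who have (or simulate) repeated
conversations per person over months.

## What it computes

For each conversation (one phone call's participant-side text, pre-tokenized
with lemmas and part-of-speech tags):

* **Word repetition** — the reciprocal of Honoré's statistic
  `HS = 100·log V / (1 − V_uni/U)` on the lemma stream (`V` tokens, `U`
  types, `V_uni` hapax legomena); 0 means no repeated vocabulary.
* **Topic repetition** — a biterm topic model (BTM) is fitted to all
  sentences by collapsed Gibbs sampling; each sliding window of `l = 3`
  sentences gets a topic-proportion vector, and the feature is the
  reciprocal of the mean Euclidean distance between window vectors.
* Both features also come in **cross-conversation pair** versions: all
  same-speaker call pairs separated by `t` days (or `n` calls) with
  `T − M < t ≤ T + M` are formed, and the features are computed on the
  merged text (word) or on cross-call window distances (topic). The interval
  center `T` (`N`) is grid-searched over 4–13 days (3–12 calls) by AUC-ROC.
* The **29 standard features** used in the connected-speech literature:
  14 part-of-speech frequencies/ratios, 3 vocabulary-richness measures
  (TTR, Brunét, Honoré), 7 syntactic-complexity measures (length metrics and
  dependency counts/distances), 5 perseveration measures (pairwise sentence
  TF-IDF cosine statistics).

Every feature is then ranked by AUC-ROC (AD = positive class,
Mann–Whitney formulation) with Cohen's d (control − AD, pooled SD), a 95%
CI, and Bonferroni-adjusted two-sided Student t p values; significance is
adjusted p < .01.

The corpus the package is calibrated to (15 Japanese seniors, 2 with AD,
1032 monitored phone calls) is private, so the package ships a seeded
generator of synthetic longitudinal corpora (`generate_corpus()`) with
controllable group differences — cross-day topic reuse governed by an
exponential memory kernel, a narrowed recurrent topic repertoire, within-call
repetition, vocabulary richness, and part-of-speech composition — plus a
packaged demographics table and reference significance patterns.

## Worked example

```r
library(convrep)

# a reduced-scale synthetic cohort with an AD repetition effect
cfg <- default_scenarios(seed = 403)$ad_effect
cfg$n_participants <- 10L; cfg$n_ad <- 5L; cfg$n_calls <- 20L
cfg <- validate_generator_config(cfg)

res <- run_pipeline(pipeline_config(
  cfg, seed = 403,
  btm = btm_config(K = 40, beta = 0.005, n_iterations = 300,
                   burn_in = 150, seed = 404)
))

head(res$ranking[, c("feature", "auc", "d", "p_adjusted")], 5)
#> # A tibble: 5 x 4
#>   feature                      auc      d p_adjusted
#>   <chr>                      <dbl>  <dbl>      <dbl>
#> 1 word_repetition_pair_days  0.780 -1.087   3.18e-13
#> 2 word_repetition_pair_calls 0.739 -0.882   1.28e-38
#> 3 topic_repetition_pair_days 0.712 -0.810   9.89e- 8
#> 4 topic_repetition_single    0.668 -0.181   1   e+ 0
#> 5 word_repetition_single     0.662 -0.499   1.81e- 2

res$best_centers$topic_days   # grid-searched day interval for topic repetition
#> [1] 7
```

Reading this: the cross-day repetition features (rows 1–3) discriminate the
synthetic AD group better than any of the 29 standard features or the
within-call repetition features; AUC is the probability a random AD sample
scores above a random control sample, and the negative d values say the AD
group repeats more. `res$curves$topic_days` holds the AUC-versus-T curve
behind the selected interval, and `res$consistency` compares the
significance pattern of the standard features against the packaged
reference. (Numbers above are from this exact seeded run; other seeds give
qualitatively similar rankings.)

The demographics table that anchors the scale of the simulation:

```r
corpus_summary(load_demographics_fixture())
#> total_calls 1032, mean_calls 68.8, mean_call_minutes 12.1,
#> mean_follow_up_months 16.1, mean_chars_per_call 1097.8, ...
```

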