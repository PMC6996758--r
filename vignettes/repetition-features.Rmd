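---
title: "Measuring word and topic repetition in longitudinal conversations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring word and topic repetition in longitudinal conversations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

People developing Alzheimer disease (AD) often retell the same stories and
reuse the same words — within one conversation and, tellingly, across
conversations held days apart. `convrep` turns this clinical observation
into a measurement pipeline for longitudinal conversation transcripts: it
extracts word- and topic-repetition features within single calls and across
pairs of calls separated by a configurable day or call-count interval,
extracts the 29 linguistic features conventionally used on connected-speech
data, and ranks every feature's power to separate AD from control speakers
by AUC-ROC and Cohen's d.

The package was calibrated to the statistical shape of a Japanese
telephone-monitoring corpus: 15 seniors (2 with AD), one 10–20 minute call
every few days for months, roughly 1100 characters of participant speech
per call, 1032 calls in all. That corpus is private; the package therefore
ships a seeded generator of synthetic longitudinal corpora with the same
scale and controllable group differences, which drives all tests.

# The features

## Word repetition

For a token stream with `V` tokens, `U` types and `V_uni` hapax legomena,
Honoré's statistic `HS = 100 log(V) / (1 - V_uni/U)` grows with vocabulary
richness and diverges when every type is a hapax. Its reciprocal `1/HS`
is the word-repetition feature: 0 for a fully hapax document, larger the
more the speaker repeats. The pair variant concatenates the two calls'
streams first, so words reused *across* the calls count as repetition.
`1/HS` of the merged stream is not always at least the single-call value —
once a document has no hapax left, merging only inflates `log V` — so the
package makes no such claim; direction checks in the tests use constructed
high/low-repetition documents.

## Topic repetition

Sentences are short, so topics are modeled with a biterm topic model (BTM):
every unordered within-sentence word pair (biterm) carries one topic
assignment, fitted by collapsed Gibbs sampling on all sentences of the
corpus at once. A single global model is fitted and reused for every
conversation so that topic vectors are comparable across calls — a
requirement for cross-pair distances.

A conversation of `L` sentences yields `L - l + 1` sliding windows of
`l = 3` consecutive sentences. Each window's topic proportions average the
per-biterm posteriors `P(k|b) ∝ θ_k φ_{w1|k} φ_{w2|k}` over the window's
biterms, which are extracted **per sentence** and pooled — pairing words
across sentence boundaries mixes topics and was measurably noisier.
The topic-repetition feature is the reciprocal of the mean Euclidean
distance between window vectors: all unordered window pairs within one
conversation (overlapping windows included — exclusion is not obviously
right and is noted as an open choice), or all cross pairs between two
conversations. Identical windows would give an infinite value; the mean
distance is floored at `epsilon = 1e-6` and the result flagged `capped`.

## Standard features

The 29 conventional features comprise 14 part-of-speech features
(frequencies of noun/verb/adjective/auxiliary/conjunction; ratios of the
seven analyzed tags; noun:verb; pronoun:noun), 3 vocabulary-richness
features (TTR, Brunét's index, HS), 7 syntactic-complexity features
(mean sentence length, sentence/word/character counts, dependency count,
average dependency distance per sentence, total dependency distance), and
5 perseveration features from pairwise sentence TF-IDF cosines.

Conventions worth stating:

* Ratios with a zero denominator are `NA`, never silently zero; the
  infinite-HS sentinel is likewise treated as missing by the statistics.
* Dependency features are computed on the *unfiltered* sentences, because
  head indices refer to original token positions and no published remapping
  rule exists for filtered text; all lexical and topic features use the
  filtered stream (numerals, symbols and stop words removed; the stop-word
  list is a configuration artifact, packaged but never hard-coded).
* TF-IDF uses the smoothed `idf = ln(S/df) + 1`. The bare `ln(S/df)` zeroes
  every term shared by all sentences, which would make two identical
  sentences *orthogonal* — the opposite of what a perseveration measure
  must say. The 0.3/0.5 cutoffs apply to cosine distance by default (small
  distance = repetition), with a `threshold_on = "similarity"` switch since
  the literature is genuinely split; the proportion-equal-to-zero statistic
  always applies to similarity.
* The dependency-rate slot of the syntactic set carries the distance
  variant (total distance / sentences); the count variant is computed too
  but sits outside the 29-feature registry.
* Logs are natural by default (base-10 available); every downstream use is
  rank-based, so the choice is immaterial for feature ranking.

# Pairing and the interval grid search

Pairs are all same-participant conversation pairs whose separation lies in
the half-open window `center - M < x <= center + M` (days or calls;
`M = 3`). The packaged defaults are day interval `T = 10` and call interval
`N = 7` for word repetition, `T = 7` and `N = 9` for topic repetition; the
grid search scans `T ∈ 4..13` and `N ∈ 3..12` and selects the center
maximizing AUC-ROC of the pair feature against group labels (AUC is what
the discriminative-power curves plot; an effect-size objective is available
by option). Ties go to the smallest center.

# Statistics

Group comparison per feature: equal-variance two-sided Student t (Welch by
flag), Bonferroni adjustment with family size = the feature batch
(configurable; the conventional batch is 35 = 29 standard + 6 repetition),
significance at adjusted p < .01, Cohen's d as (control − AD)/pooled SD —
so increased repetition in AD yields negative d — with a
normal-approximation 95% CI, and AUC-ROC in the Mann–Whitney formulation
with AD as the positive class, ties counted half, and no folding (an
anti-predictive feature reports AUC < 0.5; the folded value is printed in a
separate column). The sampling unit is the conversation for single features
and the pair for pair features: pairs from one participant are *not*
independent, so the reported n overstates the effective sample size — the
ranking is faithful to this convention and prints n per unit so the caveat
is visible.

# The synthetic generator

`generate_corpus()` emulates the monitoring-service data's statistical
structure, not its language. Per participant a call schedule is drawn (one
call every 3–7 days); per call a sentence count (negative binomial, mean
18); per sentence a topic, by one of three mechanisms:

1. with probability `p_within`, continue the current topic episode (repeat
   the previous sentence's topic) — this applies identically to fresh and
   reused topics, so a call's run-length structure never depends on the
   reuse mechanism;
2. otherwise sample a past call with probability proportional to the memory
   kernel `r(s) = a·exp(-s/λ)` at its lag (nearer calls are more
   accessible to memory), and with probability `r(s)` reuse one of that
   call's topics;
3. otherwise draw a fresh topic from the participant's base topic
   distribution. A new episode never repeats the episode it directly
   follows — that continuation is exactly what `p_within` models — but
   may re-raise any earlier topic of the call.

`measured_reuse_rate()` is an unbiased estimate of `r(s)` under the
weighted source sampling, because the Bernoulli trial at lag `s` always
uses `r(s)`; the weighting only changes how many trials each lag receives.

Two further mechanisms shape the distribution topics are drawn from:

* **Repertoire narrowing.** Each participant's base distribution is a
  symmetric Dirichlet draw; a small AD concentration
  (`base_topic_conc_ad`) produces the narrow recurrent story set described
  clinically for AD speakers, and carries the group separation at every
  pairing interval. Per-sentence kernel reuse alone is far too dilute to
  register in `l = 3` window features at a realistic corpus size — we
  verified this against ground-truth topic vectors, not just against the
  fitted model.
* **Topic drift.** Between calls, each topic of the base distribution
  moves its mass to a fresh topic with probability
  `1 - exp(-gap/topic_drift_days)` (both groups; conversation content
  tracks life events). Overlap between two calls therefore decays with
  their lag while the repertoire stays exactly as narrow, and the AD
  kernel's longer memory re-raises old topics against the drift. The
  decaying right flank of the AUC-versus-interval curve comes from this
  drift; the rising left flank comes from the control kernel's short,
  strong recency reuse contaminating small intervals.

Tokens are then slotted into dependency templates composed of one-verb
clauses (every non-verb token attaches to its clause verb, clause verbs
chain, the last is root). Noun/verb/adjective/adverb slots draw from the
chosen topic's word distributions restricted to the group's *active
vocabulary fraction*; noun slots may surface as pronouns; sentences may
open with a conjunction — these three dials create the vocabulary-richness
and part-of-speech group differences. Lemma equals surface; no morphology
is simulated. Every topic decision and reuse trial is logged in a
ground-truth table so tests never re-infer latent structure.

What the generator does *not* emulate: grammaticality, discourse
coherence, morphology, disfluencies, transcription noise, AD progression
over follow-up, or communicator speech. Passing tests on this corpus show
that the pipeline measures what the generator encodes at realistic scale
and noise — they are not evidence about real Japanese conversations.

## Scenarios

* `null` — groups share every parameter; group labels are exchangeable by
  construction. Used to calibrate specificity: no feature should reach
  adjusted p < .01 and no AUC should leave the chance band. Participant
  idiosyncrasy is kept small (near-uniform base topic distributions,
  per-component Dirichlet 8) precisely so that conversation-level
  statistics are not wrecked by 5-participants-per-group cluster effects.
* `ad_effect` — the AD group reuses topics across days much more and for
  longer (slowly decaying kernel), repeats within calls slightly more, uses
  a smaller active vocabulary, and substitutes pronouns for nouns and
  inserts conjunctions at elevated rates. Kernel amplitudes are high
  (controls re-mention very recent topics often; AD re-tells over weeks):
  weak kernels produce no measurable cross-call signal at this corpus size.
  The kernel difference `r_AD(s) - r_ctrl(s)` peaks at a designed lag
  (`kernel_difference_argmax()`), which the AUC-versus-T curve should
  reproduce to within a couple of days.
* `repetition_only` — only the kernels differ; part-of-speech features
  should stay silent (specificity of the repetition dial).

# Numerical and design choices

* Gibbs sampling: symmetric priors `alpha = 50/K`, `beta = 0.01`, 500
  sweeps by default with point estimates from the final state (no sample
  averaging); all configurable, deterministic given the seed. The sampler
  is compiled code using R's RNG.
* The analysis default is `K = 200` topics; test and example runs use
  smaller corpora and proportionally smaller `K` (30–40) with 100–300
  sweeps, stated wherever used.
* Windows with fewer than two in-vocabulary tokens are skipped with a
  logged count, not zero-filled; conversations with fewer than `l`
  sentences contribute one short window (warned).
* Degenerate statistics (zero pooled variance, one-class candidates in the
  grid search, empty lag bins) are flagged or excluded with warnings rather
  than silently patched.
* Pipeline determinism: `run_pipeline()` seeds every stage from the config
  seed; the same config reproduces every output file byte for byte.

# Problem sizes

The bundled tests fit BTMs of K = 2–60 on corpora of up to ~160k biterms
and run the full pipeline on 10-participant, 20-calls-each corpora with
K = 30–40 and 100–300 sweeps; these sizes were chosen so the whole suite
documents the method at laptop scale while preserving every qualitative
property of the full-scale configuration (15 participants, K = 200, 500
sweeps).

# Known limitations

* AUC and t statistics on pair units ignore within-participant clustering;
  a participant-level aggregation option exists but the default mirrors the
  per-sample convention of the feature-ranking literature.
* The Bonferroni family size is the batch size by default; whether the
  original convention was 29 or 35 is not documented anywhere we know of.
* The topic features inherit BTM's stochasticity: rankings are reproducible
  only at fixed seed, and `K` well below the latent topic count of the text
  visibly attenuates cross-call topic signal.
* The synthetic generator's group effects are stylized; effect sizes on
  real data will differ, and the packaged reference significance patterns
  are a transcription for consistency *counting*, not a meta-analysis.
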