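---
title: "Methods: hybrid crisis detection and emotion trajectories in peer support chats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid crisis detection and emotion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisischat)
```

## The setting

`crisischat` analyses transcripts from moderated digital peer support (DPS):
synchronous small-group live chats of up to five participants plus a trained
human moderator. Two detection channels watch every chat for suicidal
ideation (SI): an AI classifier that raises a *crisis flag* on risky
messages, and the moderator, who — prompted by the flag or by their own
judgement — poses a scripted risk-assessment *protocol question*. Users who
discuss suicidality but deny intent are labelled **passive SI**; users who
affirm intent or cannot commit to safety are labelled **active SI** and
receive an immediate *referral* to crisis resources. Alongside detection,
every user message carries scores (1–10, integer) for five emotions —
despair, loneliness, helplessness, depression, and optimism — with an
absent score meaning the emotion was not detected (a 0 is never stored).

The package implements the analysis surfaces such a service's evaluation
needs, plus a synthetic corpus generator that reproduces the statistical
structure those analyses assume, so the entire pipeline runs and is tested
without access to private chat data.

## Detection evaluation

The benchmark truth for the AI flag is the **moderator's protocol
initiation**, not the session's final SI label: a session where only the AI
flagged is a false positive even if it carries an SI label, because the
question is whether the AI agrees with the human assessment. Each session
contributes one confusion cell (TP both, FP AI-only, FN moderator-only,
TN neither); order within the chat is irrelevant for counting and matters
only for latency. From the counts we report sensitivity TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), negative predictive value
TN/(TN+FN), and accuracy (TP+TN)/n — as exact fractions plus 2-decimal
percentages (round-half-even). A zero denominator yields an explicitly
flagged undefined metric, never a silent 0.

Timing uses two anchors per session: T1, the AI crisis flag, and T2, the
moderator's protocol question. `flag_latency_stats()` summarizes the signed
difference T2 − T1 over sessions holding both anchors; negative values
(moderator first) are included in the mean and SD, and `p_ai_first` is the
fraction with T2 − T1 > 0. `referral_latency_stats()` measures, in
active-SI sessions, the delay from the last protocol/safety question to
the referral event. Prevalence is reported against both denominators in
use — user visits and chat sessions — clearly labelled, with the
passive:active ratio and monthly series.

## The synthetic corpus generator

`generator_config()` holds every distribution the corpus is drawn from; the
defaults are the study conditions the analyses are calibrated against
(SI prevalence 1.98%/1.21% of visits, AI flag sensitivity 12602/14401 and
false-positive rate 14735/155401 against the moderator benchmark, AI-first
ordering 81.26%/77.52%, follow-up latency mean/SD 71.32/89.00 s active and
79.87/95.71 s passive, referral delay 245/557 s, per-group begin/end
emotion levels, phrase lexicons with their published frequencies, 30%
demographic disclosure). Quantities the study does not report needed a
choice, made once and kept: messages per user 3 + Poisson(5) (mean 8,
minimum 3 so every visit meets the inclusion rule), moderator messages
1 + Poisson(3), exponential inter-message gaps with mean 30 s, a uniform
month distribution, an eight-topic categorical distribution, per-message
emotion noise SD 0.6, probability 0.25 that a score is absent, and SI
disclosure beginning at the discloser's third own message.

Design notes, in the order they matter:

* **Prevalence without collisions.** A session with k users becomes an
  SI session with probability k × (per-visit prevalence), and the discloser
  is uniform among its k users. The expected per-visit rate then equals the
  configured prevalence exactly while each session has at most one
  discloser. This requires (max k) × (total SI prevalence) ≤ 1, which the
  config validator enforces.

* **Latency shapes.** All printed latency SDs exceed their means, ruling
  out an untruncated normal; positive latencies are drawn from a lognormal
  moment-matched to the printed mean and SD (a zero-truncated normal is a
  config switch).

* **Signed follow-up calibration.** The follow-up difference T2 − T1 is a
  two-component mixture: with the configured AI-first probability p it is
  +L⁺, otherwise −L⁻, where L⁻ (the moderator's head start when the human
  wins the race) defaults to a lognormal with mean 30 s and SD 30 s, and
  the L⁺ lognormal is solved so that the *overall* signed mixture has
  exactly the configured mean and SD. A single latency distribution used
  symmetrically in both directions cannot do this: flipping its sign in
  (1 − p) of the sessions would drag the overall mean down to (2p − 1)
  times the printed value, so the printed mean, printed SD, and printed
  ordering probability could not all hold at once. The mixture honours all
  three by construction; the calibration is checked for feasibility
  (non-negative positive-branch variance) at config validation. When the
  moderator is first, the head start is redrawn in the rare case it would
  precede the session start.

* **Emotion trajectories.** Each visit × emotion draws a begin and an end
  level from normals truncated to the interval 1–10 and moment-matched so
  the *truncated* distribution hits the configured mean and SD — clipping
  an unbounded normal instead would inflate the low end means (about +0.1
  at an end level of 3.7, which is outside a 3-standard-error recovery band
  at the sample sizes the tests use). The latent level moves linearly from
  begin to end across the user's messages, matching the linear-interpolation
  reading of trajectories downstream; momentary non-monotonicity enters
  only through the per-message noise. Scores are the latent value plus
  noise, rounded, clamped to 1–10, and dropped with the configured absence
  probability.

* **Text.** Messages are filler drawn from a ~250-word neutral vocabulary;
  from the disclosure message on, each discloser message additionally
  embeds one lexicon phrase sampled with the published frequency weights.
  The vocabulary is deliberately large and disjoint from the lexicon
  tokens so individual filler words stay low-frequency within a session —
  the property that makes frequency-based phrase ranking meaningful. No
  language-model text is generated; realism is limited to lexicon
  injection.

* **Demographics.** Disclosure (default probability 0.30) is sampled
  independently of group — whether non-disclosure correlates with SI status
  is unknown, so independence is the explicit simplifying default — while
  the category distributions depend on the discloser's SI class. Ages are
  a shifted lognormal (minimum 13) moment-matched to the per-class mean
  and SD, so the mean and SD are honoured but the median is approximate.

What the generator does **not** emulate: real conversational language and
topic-emotion dependence, users recurring across sessions, seasonal
structure in monthly counts, moderator-initiated protocols in non-SI
sessions (the false-positive construction puts AI-only flags there
instead), and any dependence of message counts or gaps on SI status.
Passing parameter-recovery tests therefore shows the *pipeline* is
correct, not that real chats satisfy these simplifications.

## Trajectory analysis

The unit of analysis is the user visit. A visit enters the trajectory
analysis for an emotion only if the maximum available score over the focal
user's first 3 messages reaches 5 — conversations must *begin* with
measurable distress, so that trajectories track an emotional concern
rather than greetings. The threshold is applied per emotion, so each
emotion analyses a different subset of conversations. For optimism (where
a low score is not distress) the default filter is the maximum over the
four negative emotions. Active-SI visits and sessions are always excluded:
the crisis referral changes the structure and goal of those chats, so
their trajectories are not comparable.

A user's m scored messages are placed at progression i/(m−1) and connected
by straight lines; curves are read off a common grid of 101 points
(0%, 1%, …, 100%) — fine enough that piecewise-linear curves between
knots at any m ≤ 101 are represented without additional error. Knots are
placed by scored-message order, not wall-clock time, matching the use of
normalized message progression as the time covariate downstream. Visits
with fewer than two scored messages are skipped with a logged reason.
Aggregation is a pointwise mean and SD. The begin-to-end percent change is
(begin − end)/begin × 100 for negative emotions (a reduction) and
(end − begin)/begin × 100 for optimism (an increase), taken on the
aggregate curve's endpoints. Published matched-cohort reduction
percentages are *not* reproduction targets here: they derive from a
matched subset whose composition (and hence denominator) is not
recoverable, so the package's tests assert parameter recovery of the
generator's configured levels instead.

## Matching

Comparability between arms (e.g. passive-SI vs non-SI visits) is built by
propensity-score matching on two covariates: initial emotional intensity
(the eligibility maximum over the first three messages) and conversation
topic (one-hot, reference level = most frequent topic, for determinism
under refactoring). The logistic propensity model is fitted by IRLS to a
gradient norm below 1e-8 (at most 100 sweeps); perfect separation stops
with an error advising the ridge switch (an L2 penalty, default 1e-6 when
enabled, intercept unpenalized). Scores are clipped to [1e-12, 1 − 1e-12]
before the logit so saturated fits cannot produce infinities.

Matching is 1:1 greedy nearest-neighbour without replacement on the logit
scale with a caliper of 0.01; pairs farther apart are excluded. Greedy
matching requires a processing order: treated units are
processed in a random permutation under the pipeline seed — the order is
not specified by the method, and randomization avoids systematic order
bias while remaining reproducible. Equidistant controls tie-break to the
lowest control id. Balance is reported as standardized mean differences
(pooled-SD denominator) before and after matching. One propensity model is
fitted per comparison × emotion — the eligible subset differs per emotion,
so a global model would mix eligibility strata.

## Group statistics

Baseline comparisons follow the published operationalization: users with
at least five messages in the room, baseline = the score carried by the
user's *first* message (visits whose first message has no detected score
are excluded; zero scores never enter), ending level from the last message
symmetrically. Group baseline differences use the Mann–Whitney U test —
appropriate for an ordinal 1–10 scale — computed from midranks. For small
samples (n_a·n_b ≤ 200) the two-sided p-value is exact by enumeration of
the permutation distribution of the rank sum *conditional on the observed
ranks* (a dynamic-programming convolution over doubled ranks, valid under
ties where classical exact tables are not); larger samples use the normal
approximation with tie-corrected variance and continuity correction.

Trajectory slopes are compared by ANCOVA: ordinary least squares of score
on normalized progression, group, and their interaction, the interaction
being the between-group difference in emotional-change rate; its two-sided
p-value uses t with n − 4 degrees of freedom. Points entering the model
are the grid-resampled curve values, equally many per visit, so long chats
do not dominate (a raw-message alternative is available through the
lower-level functions). Points are treated as independent — session-level
clustering of residuals is deliberately ignored to mirror the analysis
design this package operationalizes; a cluster-robust option is a natural
extension but is not the default. Two-sided p-values throughout.

## Phrase mining

Candidate phrases are 2–5-token windows of lowercased,
punctuation-stripped text (contractions stay whole, matching the published
phrase forms). Within each discloser message, candidates are scored
against the session context, case-insensitive duplicates removed, and the
top k (default 3) kept; counts across sessions of one SI class form the
frequency table, with rows below frequency 2 dropped and descending-
frequency, alphabetical-tie ordering. The published pipeline ranked
candidates by cosine similarity to a pretrained sentence embedding; that
ranker sits behind a pluggable interface, and the shipped default is a
term-frequency cosine with optional idf token weights
(`tf_cosine_ranker(corpus_idf(corpus))`, the default inside
`phrase_frequency_table()`). The idf weighting is the dependency-free
stand-in for embedding salience: tokens present in nearly every session
(small talk) are down-weighted, so distinctive phrases rank first; a pure
within-session term-frequency cosine is available by passing
`tf_cosine_ranker()` and is measurably worse at separating injected
phrases from filler. Ranking is deterministic given the ranker; tied
scores keep first-occurrence order. Whether "2 to 5" described token
length or candidate count was ambiguous in the source description; token
length is used, consistent with the published 3–4-token phrases, and the
per-message candidate count is configurable via `top_k`.

## Pipeline, seeding, determinism

`run_analysis()` chains every stage — corpus, detection, demographics,
per-group trajectory curves, matched comparisons, phrase tables — into a
report bundle with a manifest of md5 checksums. A single master seed fans
out to per-stage child seeds by stable string hashing of stage names, so
inserting a stage never perturbs another stage's randomness, and identical
config + seed reproduces byte-identical outputs. Stage logs carry record
counts in and out of every filter so the inclusion rules are auditable.
Two inclusion thresholds coexist deliberately: the ≥3-message rule is a
corpus-validity check (`validate_corpus()`), while the ≥5-message rule is
the baseline-analysis filter (`baseline_comparison()`); they answer
different questions and are configured independently rather than
reconciled.

## Problem sizes used in tests

The shipped test-suite sizes are chosen for statistical power, with
SI-enriched configurations where SI sessions are the scarce resource:
12,000 single-user sessions (≈5,000 per SI class) for timing-parameter
recovery; 3,000 mixed-size sessions for trajectory, baseline and matching
recovery; 20,000 sessions at default rates for prevalence recovery;
500 replicates of 400-session ANCOVA fits for the type-I-error check; and
the acceptance script regenerates 23,000 single-user SI-dense sessions.
All stochastic recovery checks use 3-standard-error bands (binomial or
t-based as appropriate) plus small explicit allowances where construction
introduces a known, analysed bias (e.g. the redraw of moderator head
starts that would precede the session start shifts the follow-up mean by
well under one second).

## Known limitations

* The generator's independence assumptions (topics vs emotions, disclosure
  vs group, message counts vs SI) are simplifications; analyses of real
  corpora should expect confounding the synthetic tests cannot reveal.
* The ANCOVA ignores within-session correlation; its p-values are exact
  only under the independence it assumes.
* Published matched-cohort percent changes and interaction p-values are
  not reproducible from summary statistics alone and are out of scope as
  numeric targets.
* The default phrase ranker is lexical; swapping in an embedding model via
  the ranker interface is the intended path for semantic fidelity.
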