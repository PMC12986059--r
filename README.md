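# crisischat

Analysis toolkit for **moderated digital peer support (DPS) chat
transcripts** in which an AI classifier and a human moderator jointly watch
for suicidal ideation (SI). It is written for service evaluators and
digital-mental-health researchers who need to answer, from transcript
event streams:

1. **How well does the AI flag agree with the human benchmark?** Each
   session falls into one confusion cell — TP (AI crisis flag and
   moderator protocol question both present), FP (AI only), FN (moderator
   only), TN (neither) — and the package reports
   sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
   precision = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/n.
2. **How fast is the human follow-up?** Signed latency T2 − T1 between
   the AI flag (T1) and the moderator's risk-protocol question (T2),
   including the sessions where the moderator was first, plus the delay
   from the final safety question to the crisis referral.
3. **How prevalent is SI, and who disclosed demographics?**
4. **Do emotions improve over a chat, and equally across groups?**
   Per-message 1–10 emotion scores (despair, loneliness, helplessness,
   depression, optimism) are mapped onto a 0–100% conversation-progression
   scale by linear interpolation; groups (passive-SI vs non-SI, SI-exposed
   vs non-exposed) are compared after 1:1 propensity-score matching
   (logistic model on initial intensity + topic, greedy nearest neighbour
   without replacement, caliper 0.01 on the logit scale) via Mann–Whitney
   baselines and an ANCOVA group-by-time interaction.
5. **What language distinguishes active from passive SI?** 2–5-token
   n-gram phrase tables ranked by a pluggable scorer (default:
   term-frequency cosine with idf weighting).

Because real transcripts of this kind are private, the package ships a
**calibrated synthetic corpus generator** (`generator_config()` /
`generate_corpus()`) whose defaults encode the published operating points
of such a hybrid system (SI prevalence 1.98%/1.21% of visits, AI
sensitivity 87.51% against the moderator benchmark, AI-first ordering
81.26%/77.52%, follow-up latency 71.32/89.00 s active and 79.87/95.71 s
passive, referral delay 245/557 s, group-specific begin/end emotion
levels, SI phrase lexicons, 30% demographic disclosure). Every analysis
stage is tested by parameter recovery against this generator.

## Worked example

```r
library(crisischat)

cfg    <- generator_config(n_sessions = 2000, seed = 42)
corpus <- generate_corpus(cfg)
corpus
#> <chat_corpus>
#>   sessions: 2000 (passive SI 133, active SI 78)
#>   user visits: 6002 | messages: 56116 | flag events: 702

detection_metrics(confusion_counts(corpus))
#> AI flag performance against the moderator benchmark
#>   sensitivity   86.26%
#>   specificity   91.45%
#>   precision     54.33%
#>   npv           98.26%
#>   accuracy      90.90%

flag_latency_stats(corpus, "passive")
#> latency over 112 sessions: mean 77.27 s, sd 86.39 s, AI first in 75.00%

prevalence_summary(corpus)
#> SI prevalence over 6002 visits in 2000 sessions
#>   passive 133 (2.22% of visits) | active 78 (1.30% of visits)
#>   passive:active ratio 1.7:1
#>   exposure: 753 visits (12.55%) in chats with an SI discloser
```

The detection numbers are estimates of the generator's configured
operating point: sensitivity 86.26% estimates the configured 87.51% from
211 SI sessions, the 77.27 s mean follow-up estimates the configured
79.87 s for passive SI, and "AI first in 75.00%" estimates 77.52% — all
within sampling error at this corpus size. At 20,000+ sessions the
estimates tighten onto the configured values (that recovery is what the
test suite asserts).

A matched trajectory comparison on an SI-enriched corpus:

```r
cfg2 <- generator_config(n_sessions = 3000, seed = 7,
                         users_per_session = c("1" = 0.4, "2" = 0.3, "3" = 0.3),
                         prevalence = list(passive = 0.25, active = 0.05))
co2 <- generate_corpus(cfg2)
set.seed(1)
trajectory_comparison(co2, "depression")
#> depression trajectories: passive_si (n = 1167) vs non_exposed_non_si (n = 1167)
#>   begin -> end: 6.56 -> 3.90 (treated), 6.59 -> 3.50 (control)
#>   reduction: 40.5% (treated), 47.0% (control)
#>   ANCOVA group-by-time p = 7.304e-73
```

Matching equalizes the arms' initial intensity (begin values 6.56 vs 6.59
after matching), both arms improve substantially, and the interaction
p-value reflects that the generator's configured end levels genuinely
differ between these groups (3.74 vs 3.29) — at 1,167 pairs the ANCOVA
resolves that slope difference decisively.

The full report bundle (detection JSON, demographics, trajectory CSVs,
balance tables, comparison results, phrase tables, checksummed manifest):

```r
run_analysis(analysis_config(generator = cfg, seed = 1), "report/")
```

or from a shell: `Rscript inst/scripts/crisis-chat run --seed 1 --out report/`
(subcommands: `generate`, `evaluate-detection`, `trajectories`, `match`,
`compare`, `phrases`, `run`).

## Corpus file format

`write_corpus()` / `read_corpus()` use UTF-8 JSON-lines: one record per
line with a `record` field naming the table —

```
{"record":"session","session_id":"S1","month":2,"topic":"anxiety","si_label":"passive","si_discloser":"u1"}
{"record":"visit","session_id":"S1","user_id":"u1","group":"passive_si","gender":"female","race":null,"age":19}
{"record":"flag","session_id":"S1","source":"ai","kind":"crisis_flag","t":30}
{"record":"message","session_id":"S1","user_id":"u1","role":"participant","index":0,"t":10,"text":"...","despair":6}
```

Emotion scores are integers 1–10; absence (`null`/omitted) means "not
detected" and a 0 is never serialized. Times are seconds since session
start. Serialization is sorted and deterministic (equal corpora produce
byte-identical files); `write_corpus_csv()` exports a flat
one-row-per-message CSV for spreadsheets.

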