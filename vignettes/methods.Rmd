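---
title: "Neighborhood-based antihypertensive treatment recommendation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-based antihypertensive treatment recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnrec)
```

`htnrec` recommends a first-line single-drug antihypertensive treatment for
a target patient by pooling the observed outcomes of similar patients in a
routine-care training database, then labeling and optionally filtering the
ranked options with structured contraindication rules. This vignette
explains the underlying models, the tunable parameters and their defaults,
what the synthetic benchmark does and does not show, and the design
decisions taken where the method description leaves room.

**This package is a research prototype; its shipped rule base is synthetic
and must not inform clinical decisions.**

## Training points: initial-treatment episodes

The unit of evidence is one patient's *initial-treatment episode*. From a
date-ordered visit sequence with an untreated baseline (V0), the first visit
with a prescribed antihypertensive opens the episode, and the episode runs
through the maximal contiguous block of visits under that same treatment; a
treatment switch truncates it. Restricting to the initial episode is the
wash-out surrogate: it is the only stretch where the observed outcome can be
attributed to a single drug class. Three outcomes are extracted per episode:

* `delta_sys`, `delta_dia` — blood-pressure change (mmHg) from the baseline
  reading to the *last* reading of the episode (negative = improvement).
  The read-off visit is a design choice: the last episode visit carries the
  most treatment exposure.
* `endpoint_reached` — whether that final reading is at or below
  140/90 mmHg. The bound is **closed** (`<= 140` and `<= 90`): hypertension
  is defined as pressure *above* 140 and/or *above* 90, so exactly 140/90 is
  at target. A strict-bound variant is available
  (`endpoint_reached(..., closed = FALSE)`) but is not the default.

Patients with no treated visit, or whose episode lacks a usable
blood-pressure reading, contribute no training point; we deliberately do not
impute. Age enters the feature vector as completed years at the episode's
first treated visit; BMI is recomputed from height and weight when both are
recorded.

## Patient similarity and neighborhoods

Similarity between the target and database patient *j* is the simple
matching coefficient over the K schema attributes: the fraction of
attributes that match, with exact (case-sensitive) equality for categorical
attributes and the closed interval `x_{k,j} ± Δ_k` for numeric ones. Because
the interval is symmetric and closed, centering it on the database patient
is equivalent to centering it on the target; the test suite asserts this.
The neighborhood is the set of patients matching on *all* attributes
(`eta_j = 1`) — a sharp, interpretable "personalized cohort" rather than a
soft weighting.

Two schema configurations matter in practice:

* `default_schema()`: gender, age ± 5 years, BMI ± 2.5 kg/m². The BMI
  half-width is half the width of a WHO BMI class; the method description
  this package follows prints the BMI interval without a number, so the
  value is an explicit, configurable package default.
* gender + age ± 5 only — the configuration used by the evaluation
  benchmark, which gives usefully large neighborhoods at realistic database
  sizes.

Missing attribute values count as a mismatch by default (a conservatively
smaller neighborhood); `missing_policy = "renormalize"` instead averages
over the attributes observed on both sides. A schema with zero attributes
makes every patient similar, so the local engine degenerates exactly to the
global one — asserted as a test.

## Outcome prediction and ranking

Scores are `h = eta / ||eta||_1 · A` over the binary patient–therapy matrix
`A`. In `"pop"` mode `A` marks any application of a treatment; scores are
then the treatment distribution in the neighborhood and sum to 1. In
`"mean"` mode (the evaluated default) `A` additionally requires that the
endpoint was reached, so the literal formula yields the *joint* frequency
P(treated with m AND reached 140/90) over the neighborhood. Reading the
score as "the chance to reach the endpoint under m" suggests conditioning on
treatment application instead; that variant
(`engine_config(conditional = TRUE)`) is provided but off by default — the
default implements the formula as written, and the joint frequency has the
sensible property of discounting treatments with thin support.

Only treatments applied at least once in the neighborhood are eligible;
globally common treatments unseen in the neighborhood are *not* offered.
Ties in the ranking are broken by larger support count, then lexicographic
treatment code — the method description is silent here, and a deterministic
ranking is a precondition for reproducible evaluation.

An empty neighborhood yields an explicit no-recommendation result by
default; `fallback_on_empty = TRUE` substitutes the global engine and flags
the fallback in the diagnostics. Refusal is the default because silently
widening the scope changes the clinical meaning of the recommendation.

## Contraindication rules and post-filtering

Rules are flat structured records: treatment, trigger type (comorbidity /
condition / comedication), trigger code, level (absolute / relative),
description and source. A rule fires when its trigger code is present in the
corresponding context set of the target; per treatment the most severe
matched level wins, with every matched rule retained as display evidence.
"Warnings" from source material are modeled as relative-level evidence
rather than a third severity level.

The `-eb` engines filter at level `absolute` (optionally
`absolute_relative`) **before** top-N truncation, so the presented list
still contains up to N viable options. Filtering never reorders or rescores
survivors. Threshold-type conditions (e.g. advanced age) are expected as
precomputed boolean context codes (`AGE_OVER_65`-style) supplied by the
caller; the rule engine itself compares codes only.

## Vignette-panel evaluation

Each expert contributes a one-hot choice per vignette. For a top-N engine
list, agreement with an expert is the indicator inner product (1 iff the
expert's choice is in the list). `agree_all` averages the per-expert hit
rates; its dispersion across experts is reported alongside. `agree_any`
scores against the elementwise **union** of the expert one-hots. The phrase
"conjunction" would make `agree_any` at most `agree_all` and zero for any
disagreeing panel — contradicting both the name and the orderings such
evaluations report — so the union reading is implemented; this is the one
prominently recorded interpretation decision. `agree_majority` scores
against all treatments tied at the maximal vote count (5 experts over 5
classes can tie 2–2–1). Structurally `agree_any >= agree_all` and
`agree_any >= agree_majority`, and all metrics are monotone non-decreasing
in N; both are asserted as properties.

Neighborhood-size diagnostics report mean, SD and IQR, so a comparison
against externally reported "mean (dispersion)" figures is possible
whichever dispersion statistic they used.

## The synthetic benchmark

The generator emulates the *structure* of a routine-care hypertension
database: 2–5 visits per patient, untreated hypertensive baseline
(systolic > 140 or diastolic > 90), one persistent treatment from V1 on, and
a final reading drawn on the side of 140/90 determined by first sampling the
endpoint Bernoulli — this keeps the planted effect probabilities exactly
calibrated, at the price of piecewise-uniform rather than physiologic
blood-pressure values. Defaults (all config-exposed):

* J = 1000 patients; gender balanced; age uniform on 35–85; BMI uniform on
  19–36; visit counts uniform on 2–5.
* Two subgroups: S1 = women under 60 (about a quarter of the population),
  S2 = everyone else. Per subgroup one best treatment with endpoint
  probability 0.8 (S1: ARB, S2: ACE inhibitor), one second-line with 0.3
  (S1: calcium channel blocker, S2: diuretic), and a 0.05 background rate
  for the rest. The 0.8-vs-0.3 gap defines the planted effect; the low
  background keeps the second-line option identifiable in neighborhoods of
  roughly a hundred patients, which is what the post-filtering benchmark
  exercises.
* Treatment assignment uniform across the five classes, independent of
  subgroup — physicians' historical choices carry no signal, so any
  recovery is attributable to the outcome data.
* Planted contraindications (30% carrier rate each): pregnancy in S1
  (absolutely contraindicating ARB and ACE inhibitors, matching the demo
  rules) and a history of angioedema in S2 (contraindicating ACE
  inhibitors). Each blocks its subgroup's best treatment, which is what
  makes the `-eb` engines visibly better than their unfiltered
  counterparts.
* Benchmark vignettes draw ages from the interior of the population range
  (40–80) — classic mid-range cases whose ±5-year similarity window is
  fully supported by the training population.
* Simulated experts: the oracle policy picks the subgroup-best treatment
  that is not absolutely contraindicated by the vignette's context; the
  noisy policy errs uniformly with probability ε, chosen for analyzability
  (its pairwise inter-rater agreement has the closed form
  `(1−ε)² + ε²/(M−1)`, which the tests verify at n = 2000). Neither policy
  is a claim about real physicians.

What passing benchmarks show: the pipeline recovers a planted, recoverable
subgroup structure from outcome data alone, the global baseline fails the
minority subgroup, post-filtering strictly helps when experts respect the
same contraindications, and the metric orderings hold. What they do not
show: performance on real records — with correlated covariates, informative
prescribing, missingness, titration and dose changes, none of which the
generator emulates.

## Numerical and scale choices

* Neighborhood membership is decided by integer match counts (`n_match ==
  K`), never by floating-point comparison of the similarity to 1.
* Prediction-oracle agreement is asserted to 1e−12 (pure sums of products;
  anything looser would hide indexing bugs).
* Blood-pressure change summaries use presentational bins of width
  15 mmHg centered at 0, open-ended at the extremes; configurable.
* Problem sizes in the tests and the acceptance script (J = 1000 training
  patients, 100 vignettes, 5 experts, n = 2000 for the noise closed form)
  are chosen so each stochastic check has comfortable statistical margin at
  sub-minute runtimes.
* Seeds: every generator function is deterministic given its seed; the
  vignette panel defaults to `cfg$seed + 1` so a panel is never correlated
  with the training draw of the same configuration.

## Known limitations

Single-drug first-line recommendation only — no combination therapy,
titration or dose tracking. The similarity metric is unweighted and
unlearned. Rule content ships as a synthetic demonstration; real content
must be curated from guidelines and professional information. Cost, which
plausibly influences real prescribing, is deliberately not a ranking
criterion. The 298-vs-278 style gap between enrolled patients and usable
training points in real extractions (consent, missing follow-up blood
pressures) is modeled only implicitly: the extractor simply drops patients
without a usable episode.
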