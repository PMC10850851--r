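---
title: "Decision-supported delirium screening: model, engine, and synthetic trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-supported delirium screening: model, engine, and synthetic trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddst)
```

## The diagnostic model

The package implements a 22-item bedside operationalization of the
Confusion Assessment Method (CAM). Each item contributes evidence to one
of four features — F1 acute onset / fluctuating course, F2 inattention,
F3 disorganized thinking, F4 altered level of consciousness — and the
diagnosis is the boolean rule

> delirium ⇔ F1 ∧ F2 ∧ (F3 ∨ F4).

A feature is *present* once any of its evidence items is positive
(an error on an objective cognitive test, an endorsed symptom, or an
observed sign), *absent* once all of its evidence items are resolved
with none positive, and *undetermined* in between. Evaluated over all
2^4 complete assignments this yields 16 outcome categories, of which
exactly 3 are delirium-positive — one result screen per category in the
app workflow the package models.

```{r}
table(enumerate_outcomes()$delirium)
```

## The reconstructed item bank

The published description of the instrument states its *structure* —
22 items in inquiry/observation/selective blocks on 8 pages, answer
reminders on items 1, 2 and 5, interpretation cues on items 11–20, and
a hidden, automatically derived item 22 — but not the copyrighted item
wording or the item→feature mapping. The default bank is therefore an
explicit reconstruction: items 1–3 orientation (F3), 4–7 attention
(F2), 8–10 patient-reported symptom probes (F1), 11–13 observed altered
consciousness (F4), 14–17 observed disorganized thinking (F3), 18–20
observed inattention (F2), 21 observed fluctuation (F1), 22
record-comparison (F1). Every structural fact above is enforced by
`validate_item_bank()`; wording and page composition are configurable
through the YAML/JSON schema so a licensed instrument can be dropped in
without code changes. Where the source material gives both "9
evaluation interfaces" and "8 evaluation pages", the bank models the 8
item-bearing pages; the ninth interface is the patient-identification
screen, which carries no items.

## The adaptive engine

Administration follows page order with two kinds of automatic logic
jump:

1. **Within-feature jumps** (both modes): once a feature is present,
   its remaining items cannot change anything and are skipped.
2. **Early stopping** (`fast` mode): after every response the engine
   compares two classifications — the lower bound `classify(L)` using
   only the features currently present, and the upper bound
   `classify(U)` treating every present-or-undetermined feature as
   present. Because the diagnostic rule is monotone in the feature set,
   the true terminal classification is always bracketed by these
   bounds; when they agree the session ends.

The app flow diagram the original system used is not published, so the
stopping rule here is derived from the monotone-bound argument rather
than transcribed from a flowchart. The bound method reproduces the
classification of *any* correct flowchart, and can stop earlier than an
illustration might suggest: with every response normal, the session is
already decidable after the last F3/F4 item, since F3 and F4 both
absent preclude delirium regardless of F1/F2.

At terminalization, features left undetermined (possible only under
early stopping) are mapped to *absent* for the category label. This
cannot change the delirium classification — the decidability condition
guarantees it — but it means the fast-mode 4-tuple label may differ
from the full-mode label for the same latent responses. The
fast-vs-full equivalence tests therefore assert equality of the
diagnosis and agreement of every feature the fast session actually
resolved, not equality of labels.

**Item 22** (acute change from baseline) is never displayed. It is
injected as an `auto` response at session start and re-derived after
every submission: positive iff a most recent prior session exists in
the patient's record and the current evidence contains a *new* deficit
relative to it — a feature absent at baseline that now has positive
evidence, or an objective cognitive item (items 1–7 in the default
bank) answered correctly at baseline and failed now. With no prior
session the item is normal and the session is flagged "no baseline".
Because new evidence only accumulates, the derivation is monotone and
the rescoring loop converges in at most two passes.

## The synthetic crossover trial

The generator emulates the usability study design the analysis module
targets: 72 nurses randomized 1:1 to paper-first or app-first, three
patients per nurse per modality (432 assessments, 216 nurse-paired
sets), a 24-hour washout, and one usability questionnaire per nurse per
modality. Published results report summary statistics, not generative
parameters, so the defaults are *fitted to the summaries* and
documented as such:

* **Prevalence** 0.26. Delirious patients draw one of the 3 positive
  feature combinations uniformly; non-delirious patients draw features
  independently (defaults F1 0.12, F2 0.08, F3 0.10, F4 0.06 — modest
  isolated-feature rates chosen as clinically plausible) conditioned on
  not meeting the rule. Each present feature forces at least one
  positive latent item (per-item probability 0.6).
* **Recording errors**: each displayed item is flipped independently
  with per-item rates 15/(216·21) (paper) and 5/(216·21) (app), so the
  expected trial-wide error totals match the published 15 and 5.
* **Completion success**: Bernoulli per assessment, failure rates
  13/216 (paper) and 4/216 (app), independent of item errors — the two
  are reported separately in the source and never linked.
* **Times**: lognormal with medians 4.4 and 2.3 minutes and `sdlog`
  matched to the published IQR ratios
  (`log(q75/q25) / (2 z_{0.75})` ≈ 0.57 and 0.77). The published IQRs
  are not symmetric around the medians on the log scale, so a two-
  parameter lognormal can match the median and the IQR *ratio* but not
  both quartile locations; the median is the calibration target.
* **Likert usability**: item response = round(latent) clipped to 1–5,
  with latent = domain mean + nurse effect + item noise (equal-width
  thresholds at 1.5…4.5). Domain means start at the published
  per-domain medians and are shifted by a single per-modality constant,
  solved deterministically by `uniroot` at configuration time, so the
  *expected* questionnaire total equals the published 3.40 (paper) and
  4.35 (app). The per-domain item split (5/5/4/4/4/4 of 26 items;
  8/8/7/7/7/6 of 43) is a package choice: the published medians are
  consistent with a 7/6/3/3/3/5 split, but that sums to 27 and
  contradicts the printed total of 26, so the package uses an even
  split and treats only the totals as calibration targets. Nurse-effect
  SDs (0.40 / 0.28) approximate the published total-score SDs
  (0.43 / 0.31); the SDs are not acceptance targets.
* **Patients**: 432 assessments draw with replacement from a pool of
  148 latent patients — the published count of distinct patients — as
  the actual reuse scheme is unstated.

What a green simulation test does establish: the engine, records,
generator and analysis pipeline are internally consistent, the
generator recovers its own parameters at scale, and the analysis
reproduces the published *arithmetic* (counts, percentages, the 54→72
attrition inflation). What it does not establish: the field study's
observed usability medians, Z values, error counts or p-values as
empirical outcomes — those depend on raw nurse-level data that were
never published and enter here only as calibration defaults. Nurse
demographics (age, sex, education) are not simulated at all; the
summary reports the group split instead of demographic balance tables.

## Statistical procedures

* **Completion rates**: 2×2 tests, two-sided. The Fisher exact p sums
  hypergeometric point probabilities ≤ the observed table's; the
  chi-square uses the Yates continuity correction. The default picks
  Fisher when any expected cell is below 10 (on the published success
  table the two give ≈.045 and ≈.048; the source does not say which
  test produced its printed value, and no p-value is an acceptance
  target). A zero *row* margin is an error (an unobserved modality); a
  zero *column* margin is degenerate and returns p = 1.
* **Paired Wilcoxon signed-rank**: zero differences dropped; Z is the
  tie-corrected normal-approximation statistic, signed by the `a − b`
  direction (at n = 72 its attainable maximum is
  `(n(n+1)/4)/sqrt(n(n+1)(2n+1)/24)` ≈ 7.37, which is why published
  crossover Z values near −6.9 to −7.0 are consistent with fully
  one-sided differences). The p-value is exact — the 2^n sign-flip
  permutation distribution — whenever ≤ 10 non-zero differences
  remain, asymptotic otherwise.
* **Order effect**: one-way ANOVA on nurse totals by group; with two
  groups F equals the squared pooled-variance t statistic.
* **Sample size**: the standard two-sample normal-approximation formula
  `n/group = 2((z_{1−α/2}+z_{power}) σ/δ)^2`, rounded up, plus
  attrition inflation `ceil(n/(1−attrition))`. With δ = 1, σ = 1,
  α = .05, power = .90 the formula gives 22 per group; the published
  "54 nurses" is not reproducible from those inputs under any standard
  two-sample formula, so the package documents the formula it uses and
  exposes the inflation step separately — which does reproduce the
  published 54 → 72 enrollment exactly.

## Numerical and design notes

* Percent formatting mirrors the source's conventions: success rates to
  1 decimal with trailing ".0" dropped (203/216 → "94", 212/216 →
  "98.1"); count-style percentages to whole percents (38/148 → "26").
* All simulation randomness flows from one `set.seed(seed)` call in
  `simulate_trial()`; identical seeds give byte-identical CSVs.
* The record store keys sessions by (patient, timestamp); re-appending
  an identical key is a no-op, `latest_before()` is strictly earlier
  than its cutoff, and the admission baseline (`baseline_session()`) is
  exposed separately because both "compare with admission" and
  "compare with the previous evaluation" are sensible readings of the
  baseline-comparison workflow; item-22 derivation uses the most recent
  session.
* Heavy test loops are scaled to desk hardware: the fast/full
  equivalence check samples 10,000 latent vectors plus one
  representative per feature class; parameter-recovery runs use
  n = 5,000–10,000. The full suite completes in roughly two minutes on
  one CPU.

## Known limitations

* The default item wording is placeholder text, not the licensed
  instrument; only structure and logic are faithful.
* Learning effects across a nurse's three sequential patients and
  researcher-rater error are not modeled (the researcher's reference
  assessment is treated as ground truth).
* The Likert model's per-domain item allocation and the non-delirious
  feature rates are package choices, stated above, not published facts.
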