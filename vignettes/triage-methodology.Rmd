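---
title: "Models and design of the asavtriage toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the asavtriage toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asavtriage)
```

## The problem

In a mass-casualty incident (MCI), the first responders on scene must sort
casualties by treatment and transport priority — *primary triage* — long
before individual care is possible. The START family of algorithms
standardises this as a short decision tree over coarse vital signs, ending
in one of four categories: red (immediate), yellow (delayed), green
(minor), black (dead). The Amberg-Schwandorf algorithm (ASAV) is the
variant this package centres on: it was designed for physician-manned EMS
systems, where non-physician providers may not pronounce death, so black
may be assigned *only* on definite signs of death and every other patient
with impaired vital functions is red. Respiration is assessed in a single
step — any of a short list of distinct breathing disorders, or apnoea —
rather than by counting a respiratory rate.

Triage algorithms of this family are evaluated like diagnostic tests:
providers triage a standardised set of simulated casualties (written
"dummy description cards"), their assignments are compared with a
consensus *standard solution*, and sensitivity/specificity for the red
class, likelihood ratios, and over-/under-triage rates are reported with
confidence intervals, together with per-patient triage times. This package
implements that entire evaluation pipeline, plus a synthetic-data layer
that stands in for the human exercise, so the machinery can be exercised,
calibrated and verified end to end.

## The decision-tree engine

The engine is data-driven: an algorithm is a JSON document (`name`,
`root`, `nodes`) validated into a rooted tree. Predicates come from a
closed vocabulary of six boolean tests over the card's vitals
(`predicate_vocabulary()`); unknown predicates, dangling branches, cycles,
multiple parents, unreachable nodes and leaves without an assigned
category are all rejected with a full list of violations.

Nodes come in three shapes:

* **decision** — a predicate with an explicit branch per outcome;
* **conditional action** — a predicate with `actions` and a single `next`:
  the actions fire on "yes" and flow continues either way. This is the
  flowchart side-box ("spurting haemorrhage → indicate bleeding control,
  then continue") and is what keeps the graph a tree: modelling the same
  step as a decision node would make its two branches rejoin;
* **leaf** — an assigned category, optionally with actions.

The packaged default tree is a **reconstruction** of ASAV from its textual
description, in this order: definite death signs → black; spurting
haemorrhage → indicate bleeding LSI, continue; able to walk → green;
unconscious → indicate airway LSI → red; breathing disorder or apnoea →
red; circulation abnormal → red; otherwise yellow. Two points were
genuinely open and are package choices:

* **Circulation** is a single boolean — radial pulse absent *or* abnormal
  skin signs — because no capillary-refill or pulse-rate thresholds are
  published for this step. A transcription of the original flowchart can
  replace the packaged JSON without code changes.
* **Walking → green** precedes the consciousness/breathing/circulation
  checks, as in the rest of the START family.

A START-style comparator tree (walking assessed first) ships alongside; it
is synthetic and illustrative. Because the predicate vocabulary has no
standalone apnoea test, the comparator keeps the
black-only-on-definite-death rule rather than the classic
apnoea-after-airway-opening → black step.

The engine's correctness is established against an independently
hand-coded nested-conditional oracle over the full discretised cross
product of the vitals fields the vocabulary can read (576 combinations),
including the ASAV-specific invariant that black is assigned *iff*
definite death signs are present.

## The synthetic study

### Casualty cards

`generate_cards(n, mix, include_ambiguous, seed)` allocates `n` cards to
gold categories by exact largest-remainder quota on the mix, then samples
vitals *conditional on the category* so that the default tree provably
reproduces it (this generator–engine consistency is asserted at build
time for every deck). Narrative fields (demographics, posture, injuries
with body locations) are drawn from small per-category pools; they carry
no information the engine uses — decisions are taken on structured fields
only.

The default deck mix is 40% red / 30% yellow / 25% green / 5% black. The
true per-card distribution of the historical 40-card deck was never
published, so this is a configuration value, not a claim; it was chosen
once as a realistic certification-exercise deck (red-heavy, so that the
red-class 2×2 is well populated) and is not revisited.

One card per deck (by default) is the **ambiguous red-or-black case**:
apnoeic, pulseless, with massive torso trauma but *no* definite sign of
death — the configuration on which a consensus panel could not agree, so
both red and black count as correct. The default tree assigns it red,
which lies in its accept-set.

Gold LSI flags are defined as the indications the default tree raises on
the card (airway opening iff unconscious, bleeding control iff spurting
haemorrhage), so a zero-error simulation scores perfectly on the LSI
endpoints as well.

### Teams

`make_teams()` samples each member's employment, qualification and prior
mSTaRT-training status from composition weights shaped like the study
roster (55/76 career; career qualifications 41 paramedic / 9 EMT /
5 other; volunteer 2/3/16; training 37/16/2 and 3/15/3). Members are
sampled independently, so heterogeneous teams arise naturally; team-level
employment/training become `"mixed"` (or `"unknown"`), which the subgroup
analyses then filter out, exactly as the homogeneous-team rules require.
The staffing class (mICU / patient transport ambulance / disaster
response / excluded) is always derived from the two qualifications, never
stored.

### The error model

Simulated assignment error is a row-stochastic 4×4 confusion kernel: row =
the category the algorithm implies for the card, column = the probability
the team assigns it. LSI decisions are flipped independently with
`lsi_miss_prob`. `implied_mistriage_rates()` gives the model's population
rates in closed form (mix-weighted kernel mass on the enumerated pairs),
so parameter-recovery tests compare a Monte Carlo estimate against an
exact expectation.

`mistriage_error_model()` constructs the *simplest* kernel hitting given
targets. With only aggregate targets, all under-triage is red→yellow and
all over-triage green→yellow. With the critical rates also given, the
critical under-triage mass goes on red→yellow (remainder yellow→green)
and the critical over-triage mass on yellow→red (remainder green→yellow);
this additionally pins the red-vs-rest operating point at
sensitivity `1 − critical_under/mix_red` and specificity
`1 − critical_over/(1 − mix_red)`. The default study configuration
calibrates all four rates to the published 9.7/4.8/6.4/4.4% values, which
is why a default simulation lands near the published sensitivity and
specificity as well. These published rates are *observed human-rater
outcomes*: the simulator treats them as calibration inputs and recovers
them; it cannot re-derive them from first principles.

### The time model

Per-category triage times default to a lognormal family: strictly
positive, right-skewed, the standard first choice for service times, and
consistent with the published whole-collective mean 35.4 s exceeding the
median 35.0 s. The parameterisation matches a (mean, median) pair exactly
— `meanlog = log(median)`, `sdlog = sqrt(2·log(mean/median))` — so the
fitted means equal their targets analytically (the calibration to the
published per-category means 41.8/38.9/14.5/28.8 s is exact, not within a
tolerance). Per-category medians were never published; the default scales
each mean by the whole-collective median/mean ratio 35.0/35.4, the only
skewness information available. An empirical resampling family is
provided for when raw times exist. Run times are drawn from the model of
the card's *expected* (algorithm-implied) category, matching how the
published per-category means were tabulated.

## Evaluation definitions

* **Multi-accept cards.** Runs on the red-or-black card are concordant if
  the assignment lies in the accept-set; concordant runs count as correct
  and enter no mis-triage numerator. For the red-vs-rest 2×2 they are
  excluded entirely: the card has no single gold polarity, and exclusion
  avoids inventing one. Reports flag the concordant/discordant counts.
* **Mis-triage pairs.** Over- and under-triage are literal pair
  enumerations (see `over_triage_pairs()` and friends), not ordinal
  distances — black has no rank. Pairs in neither list (yellow or green
  assigned on a gold black, black assigned on gold yellow/green) are
  tallied as `other_mismatch`, so correct + over + under + other +
  discordant-multi-accept partitions the runs exactly; this partition and
  the equivalence with a brute-force per-run scoring loop are
  property-tested on random run tables.
* **Denominators.** Every rate uses the total runs in scope (the "6.4% of
  780" convention), except sensitivity and specificity, which use their
  own class sizes.
* **Confidence intervals.** Proportions get Wald intervals without
  continuity correction — the method that reproduces the published
  interval for 83.9% of 780 runs, (81.3, 86.5), to the printed decimal —
  clipped to [0, 1]. Likelihood ratios are reported without intervals, as
  in the source tables. `lr_pos` at perfect specificity is `Inf`;
  `lr_neg` at zero specificity is `NaN`.

## Time analysis choices

* Mean CIs use the t distribution (the conventional choice; the original
  method is unstated).
* Percentile point estimates use linear interpolation between order
  statistics (R's type-7 quantile); conventions differ across software,
  so this is stated explicitly.
* Percentile CIs use the distribution-free order-statistic (binomial)
  method: ranks `qbinom(α/2, n, p)` (floored at 1) to
  `qbinom(1−α/2, n, p) + 1` (capped at n). For constant series all
  intervals collapse to zero width.
* Group comparisons use classical one-way ANOVA on unbalanced groups with
  pooled-variance pairwise t tests under Bonferroni adjustment — the
  desktop-statistics "Bonferroni post-hoc" convention. With two groups, F
  equals the squared pooled t statistic (tested).
* The incident simulator deals casualties round-robin to teams and adds
  no travel-time model: the measured times already include tagging and
  walking to the next patient. Completion is the slowest team's total.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::with_seed`);
there is no hidden global state, and identical seeds give byte-identical
decks, rosters, run tables and study bundles. The test suite uses decks
of 8–40 cards and rosters of 2–38 teams; the parameter-recovery check
uses 5,000 runs (125 teams × 40 cards) and compares estimated mis-triage
rates against the closed-form implied rates within three Monte Carlo
standard errors; incident simulations use a few hundred replicates. These
sizes were chosen to make Monte Carlo bands tight relative to the effects
being checked while keeping the default suite quick to run.

## What passing tests do and do not show

The synthetic layer emulates the *formal* structure of a dummy-card
exercise: structured vitals, a consensus gold standard with one ambiguous
card, team composition, misclassification with tunable rates, and skewed
service times. It does not emulate clinical reality: no physical
assessment, no inter-provider variability beyond the shared kernel, no
learning or fatigue across runs, no dependence of errors on team
qualification (subgroup differences in a default simulation are sampling
noise), and no validity information about whether the gold labels
themselves reflect true patient need. Results on synthetic data therefore
validate the *machinery* — engine, estimators, intervals, planning
arithmetic — not the algorithm's clinical performance.

## Known limitations

* The packaged ASAV tree is a documented reconstruction from text, not a
  transcription of the original flowchart; the breathing-disorder list is
  configurable because its canonical content is unpublished.
* The evaluation treats runs as independent, as the source analysis did;
  there is no adjustment for repeated measures within teams or cards.
* Percentile CIs for small n can be wide and asymmetric; the
  order-statistic method guarantees coverage only approximately at the
  extreme percentiles of small samples.
* The planning mean is a first-order tool: it ignores queueing, travel
  geometry and LSI execution time (the underlying measurements
  deliberately under-represent the latter).
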