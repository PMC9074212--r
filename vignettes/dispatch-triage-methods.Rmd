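---
title: "Cost-sensitive CHAID trees for ambulance dispatch triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive CHAID trees for ambulance dispatch triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispatchtriage)
```

## The problem

When a bystander phones in a motor-vehicle crash (MVC), the emergency
medical dispatcher must decide whether to send an ambulance under lights
and sirens (L&S) — the highest-priority response — using only what the
caller can describe: the Medical Priority Dispatch System (MPDS) Protocol-29
code assigned by scripted questioning, plus observable crash
characteristics (rollover, trapped occupants, weather, road type, ...).
Two errors trade off against each other:

* **over triage** — dispatching L&S to an incident that did not need it:
  `100 · FP / (FP + TP)`, i.e. one minus the positive predictive value;
* **under triage** — withholding L&S from an incident that needed it:
  `100 · FN / (FN + TN)`, one minus the negative predictive value.

The American College of Surgeons Committee on Trauma (ACS COT) benchmark
regards under triage of at most 5% with over triage between 25% and 35% as
acceptable. Ambulance services are "front loaded": a low under-triage rate
is valued above a low over-triage rate, because the cost of a missed
time-critical patient is a life, while the cost of a false alarm is a
resource.

This package implements the full analysis pipeline: a from-scratch CHAID
(Chi-square Automatic Interaction Detector) tree grower over categorical
crash predictors, cost-sensitive leaf classification, an incremental
misclassification-cost sweep, triage-rate evaluation, and benchmark-based
model selection — together with a synthetic cohort generator built from the
embedded marginal tables of a three-year metropolitan MVC cohort
(n = 11,971 incidents, 1,771 of which needed L&S).

## Outcome labelling

Whether an incident *needed* L&S is reconstructed retrospectively as a
disjunction: the ambulance left the scene for an emergency department under
L&S, **or** anyone died on scene or in transit, **or** anyone met at least
one clinical dispatch indicator. Indicators are predicates over
interventions, medications and observations, evaluated per incident.
There is no authoritative public indicator list, so `label_dataset()` takes
a configurable rule table (JSON: name, field, operator, threshold) and the
shipped default — reduced consciousness (GCS < 13), hypotension
(SBP < 90 mmHg), intubation, adrenaline — is illustrative only, not a
clinical standard. Labelling refuses to run on incomplete clinical fields:
a missing vital sign raises an error rather than silently counting as
"no", because a silently false clause would bias labels toward not-L&S.

## The CHAID grower

CHAID builds multi-way trees on categorical predictors in two alternating
moves.

**Category merging.** At a node, each candidate variable's observed
categories start as singleton groups. The pair of groups whose 2 × 2
subtable against the outcome has the *largest* Pearson chi-square p-value
is merged, repeatedly, until every allowable pair differs at
`alpha_merge` (default 0.05) or one group remains. Nominal variables may
merge any pair; ordinal variables only adjacent groups, so merged groups
stay contiguous runs; the missing category floats and may join any group.
After the significance phase, any group smaller than `min_child` is folded
into its most similar allowable neighbour. This small-category handling is
standard in CHAID implementations and matters here: of the 52 Protocol-29
codes, several appear fewer than ten times in three years (e.g. the
confirmed-fatality code occurred once), and without folding, a tiny merged
group of rare high-fatality codes would veto *every* MPDS-rooted split via
the minimum-child-size rule.

**Split selection.** The merged r × 2 table is tested with the Pearson
chi-square (df = r − 1). Because the grouping was chosen among many, the
raw p-value is Bonferroni-multiplied by the number of ways `c` observed
categories can be partitioned into `r` groups: the Stirling number
S(c, r) for nominal variables, `choose(c − 1, r − 1)` for ordinals. The
variable with the smallest adjusted p-value splits the node if it reaches
`alpha_split` (default 0.05) and every child holds at least `min_child`
records. Ties break by declared schema order, which, with the greedy
merge's fixed scan order, makes growth fully deterministic. Growth stops at
`max_depth`, below `min_parent` (default 100; `min_child` 50), at pure
nodes, or when no split is significant. There is no re-split of merged
categories after merging, and no pruning or cross-validation: like the
analysis this mirrors, all rates are apparent (training) rates.

Defaults follow the common SPSS Decision Trees settings
(alpha 0.05 / 0.05, node floors 100 / 50); all are configurable through
`chaid_config()`.

**Costs enter at classification, not growth.** A leaf with L&S proportion
p-hat predicts L&S under costs `c_fp : c_fn` iff
`p̂ · c_fn ≥ (1 − p̂) · c_fp`, the expected-cost rule; the tie goes to L&S
(safety first), and a leaf that saw no L&S cases predicts not-L&S at any
finite ratio. Because growth ignores costs, one tree per model family
serves the whole cost sweep, and raising `c_fn` can only flip whole leaves
from negative to positive in decreasing order of p-hat — which is why every
sweep is provably monotone: under triage never rises and over triage never
falls as the ratio increases.

**Missing values and unseen categories.** Records whose value at a split
belongs to no child group (an unseen category at prediction time) follow
the child containing the missing label; if none exists they stop and are
classified by the current node's own distribution.

## Model families and the cost sweep

Five families differ only in candidates, root forcing and depth: A (MPDS
code only, depth 1), B (MPDS forced first + characteristics, depth 3),
C (characteristics only, depth 3), D (MPDS forced + characteristics,
unlimited), E (characteristics only, unlimited). Forcing the MPDS code
first mirrors a service that keeps its established dispatch codes and asks
what additional questions buy.

`chaid_sweep()` grows the family's tree once and evaluates integer cost
ratios 1:1, 1:2, ... until the first ratio with 0% under triage — the
point where every incident that needed L&S is dispatched L&S — or until
`max_ratio`, in which case the result is flagged as capped rather than
silently truncated. The default cap of 100 guards against pathological
data; end-to-end runs on the synthetic cohort pass a higher explicit cap
because a deep tree can hold a leaf with, say, 1 L&S case in 500, which
only flips at ratio ≈ 500. (The ratio needed is bounded by the largest
leaf's odds, hence by the cohort size.) Consecutive ratios with rates
equal to one printed decimal collapse into ranges ("1:13 to 1:18") in the
report table, and all rates print to one decimal place.

`select_model()` applies the front-loaded reading of "closest to the ACS
COT benchmark": degenerate all-positive rows (no predicted negatives) are
excluded, then among rows with under triage ≤ 5% the smallest under
triage wins, ties broken by smaller over triage. Full benchmark
compliance (over triage inside 25–35%) is reported as a per-row flag but
deliberately not required for selection — with over-triage rates in the
80s across the board, requiring it would select nothing, and a dispatch
service prioritises the under-triage bound.

## The synthetic cohort generator

The embedded tables give, for each Protocol-29 code and each of sixteen
crash characteristics, the count of incidents by outcome; characteristic
blocks sum short of 11,971 where values were missing, and those deficits
(0% to ~66%) are the default per-variable missing rates. Three modes:

* **fixture-faithful** — exactly 11,971 records whose (code, outcome)
  joint counts equal the embedded table (deterministic counts; the seed
  only shuffles order and draws characteristics), characteristics sampled
  from the per-outcome marginals with their missingness. Five declared
  variables (raining, speed limit, time of day, traffic control,
  intersection type) have no embedded block; they are sampled from
  illustrative urban-road distributions chosen once — identical across
  outcome classes, so they carry no signal — and the continuous time of
  day from commuter-peaked hourly weights.
* **planted-tree** — features from the pooled overall marginals, outcome
  drawn from a per-record leaf probability defined by a planted decision
  tree. The shipped two-level spec splits on trapped occupants, then
  atmosphere (trapped branch) and rollover (untrapped branch), with leaf
  probabilities 0.05–0.85 — effect sizes a grower should recover.
* **marginal-independent** — features from overall marginals, outcome
  independent at the cohort prevalence (a null for false-split checks).

What the generator deliberately does **not** emulate: the real joint
dependence *between* characteristics (they are conditionally independent
given the outcome), multi-patient incident structure, geography and time
trends. Consequently a sweep on the synthetic cohort reproduces the
analysis' structure — monotone trade-off curves ending at the all-positive
85.2%/0.0% row — but not the real cohort's interior values; the published
multi-level rates depend on the unreleased linked data's joint
distribution, and passing tests here demonstrate correctness of the
machinery, not agreement of interior rates with any real cohort.

## Numerical choices and degenerate inputs

* Chi-square statistics sum over cells with positive expected counts; a
  table with an all-zero outcome column (or a single row) is treated as
  carrying no association (statistic 0, p 1).
* Zero denominators in the triage rates yield 0%: an all-L&S policy has
  under triage 0% and an all-negative policy over triage 0%.
* Greedy merging breaks p-value ties (within 1e-12) by the first allowable
  pair in scan order; split-variable ties by schema order.
* Continuous time of day is binned at load into equal-frequency ordinal
  bins (default 10) from sample quantiles, the usual discretisation for a
  chi-square-based grower.
* Trees serialise losslessly to JSON (round-trip yields identical
  predictions) and to Graphviz DOT for inspection.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at the cohort size (11,971),
sweep monotonicity at n = 20,000, and planted-tree recovery at n = 50,000
over 20 replicates (the root variable and both first-level split variables
must be recovered; observed recovery is at or near 100%). The acceptance
script repeats recovery over 10 replicates and runs the complete
five-family sweep on the fixture-faithful cohort. These sizes were chosen
to give binomial sampling tolerances a comfortable margin around every
asserted rate.

## Known limitations

* Apparent rates only — no holdout, pruning or cross-validation, matching
  the design this package operationalises.
* The indicator rule set is illustrative; real use requires a service's
  clinically governed list.
* Exhaustive (non-greedy) optimal merging and CART-style binary splits are
  out of scope, as is record linkage between ambulance and police data.
* The Bonferroni multipliers are the classical partition counts; no
  allowance is made for the floating missing category's extra partitions
  (the adjustment is therefore slightly conservative for ordinals with
  missingness).
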