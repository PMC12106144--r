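---
title: "Modelling daily-activity routines and detecting anomalous days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily-activity routines and detecting anomalous days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`adlmonitor` models the daily routines of smart-home residents as
*dedication vectors* — the percentage of each calendar day spent in each
recognized activity — predicts the next day's vector from a sliding window of
previous days, and screens days whose prediction error is a statistical
outlier, explaining each alarm by the activities that left their normal
range. This vignette records the package's modelling assumptions, the
parameters that matter, and the design decisions taken where several
reasonable conventions exist.

## From event logs to dedication tables

Input logs carry one sensor event per line: date, time (sub-second), sensor
id, value, and a recognized activity label. The package treats activity
recognition as upstream and the label as ground truth.

**Run-end convention.** Events are instantaneous readings, so an activity is
taken to persist until the label changes: a maximal run of identical
consecutive labels becomes one interval from its first event to the *next*
run's first event (half-open coverage). This tiles the observed span without
gaps, which is what makes a dominant activity like overnight sleep occupy a
realistic ~30% of the day; ending runs at their own last event (available as
`end_rule = "last_event"`) systematically undercounts sparse activities whose
events arrive at the start of an episode. The final run of a log necessarily
ends at its own last event.

**Day framing.** Intervals crossing civil midnight are split so every piece
lies within one calendar day; durations are conserved to microsecond
precision. Timestamps are treated as naive local time — no timezone or DST
arithmetic — matching how residential logs are recorded.

**Dedication.** Per (user, day, activity) the summed seconds are divided by a
fixed 86,400 s day. Partially observed first and last days would otherwise
read as artificially idle, so each user's boundary days are dropped by
default (`drop_boundary_days`). Days inside the observation range with no
events become rows of zeros, and an activity absent on a day is exactly 0.
The catch-all label `Other_Activity` is removed after aggregation — it has no
predictable structure — and the remaining columns are *not* renormalized, so
a day's total may be below 100. The activity vocabulary is the union of
labels across all users, frozen at ingest in locale-independent (radix)
lexicographic order. Values are kept at full precision internally; CSV output
rounds to 2 decimals.

## Windowing and the evaluation protocol

The split is chronological *within* each user: the first
`floor(0.7 · m)` days train, the rest test, so both subsets contain every
user and no model ever sees a user's future. Windows are then built inside
each subset independently; the first `w − 1` days of the test stream are
therefore never labels, which is the price of a leak-free boundary. Windows
do not span gaps in the calendar (the window restarts after missing days);
`allow_gaps = TRUE` treats rows as consecutive for corpora where gaps are
recording artifacts rather than genuinely missing days.

Scores follow the per-day convention: a day's MAE (MSE) is the mean over the
t activities of the absolute (squared) error, and a dataset's score is the
mean over days; fold summaries report the mean and *population*-form
standard deviation across folds. Cross-validation partitions window samples
into chronologically contiguous blocks per user, preserving time order inside
folds; a shuffled mode exists for comparison but mixes a user's past and
future across folds and is flagged as leakage-prone. The paired t-test on
per-fold scores adopts two documented conventions for the k = 3 degeneracies:
all-zero differences give p = 1, zero-variance nonzero differences give
p = 0.

## The recurrent engine

No deep-learning framework is required: the package implements its own
sequence engine (LSTM cell, bidirectional wrapper, 1-D convolution over
time, additive attention, dense layers, inverted dropout) with exact
analytic backpropagation, verified in the test suite against numerical
differentiation to five decimals. Four architectures are exposed:

* `rnn` — 1–4 stacked LSTM layers, last hidden state into a dense head;
* `bi_rnn` — forward and backward LSTMs, final states concatenated;
* `conv_lstm` — valid 1-D convolution over the time axis (ReLU), then LSTM;
* `attention_rnn` — LSTM returning the full sequence, additive attention
  (`score = v·tanh(W·h_step)`, softmax over the `w − 1` steps, sequence
  reweighted by the alphas), then a second LSTM. The alphas are non-negative
  and sum to 1 by construction and are inspectable via
  `attention_weights()`.

Two numerical choices matter in practice:

* **Input scaling.** Dedications enter the recurrent stack divided by 100;
  percent-scale inputs saturate the gate nonlinearities under standard
  initialization. Outputs remain on the percent scale through a ReLU head,
  so predictions are never negative, matching the domain of the data.
* **Output-bias initialization.** The output layer's bias starts at the
  per-activity mean of the training labels. Optimization therefore starts
  *at* the mean baseline and spends its budget learning structure on top,
  rather than re-deriving the output scale from scratch.

**Training recipe.** The default `train_config()` is Adam with learning rate
0.1, β₁ = 0.9, β₂ = 0.999, MSE loss, batch size 128, 80 epochs. That step
size is aggressive: with short budgets Adam's update magnitude (≈ the
learning rate per step) leaves the optimizer oscillating around the optimum,
and on some seeds the net never improves on its mean-baseline starting
point. The package therefore uses a *short-budget recipe* — learning rate
0.02, 20 epochs — wherever training time is constrained (the test suite, the
acceptance script, the examples); it converges reliably across seeds at
these problem sizes. Both are plain `train_config()` calls; nothing is
hard-wired. Training is exactly seeded: initialization and batch order
derive from `config$seed`, and identical inputs reproduce identical
parameters bit for bit. Divergence to a non-finite loss aborts with a
diagnostic rather than returning garbage.

**Single-day regressors.** Classic algorithms cannot consume a sequence, so
they receive only the previous day and fit one single-output model per
activity (predictions assembled into the t-vector, negatives clipped).
"Naive Bayes" has no standard regression form; it is implemented as a
Gaussian Bayesian ridge per label (closed-form posterior mean under a
Gaussian prior), which keeps the intended "independent Gaussian assumptions
per label" character. AdaBoost is AdaBoost.R2 over depth-3 regression trees
with the weighted-median combiner. An activity whose training labels are
constant (typically all zero — rare activities) gets a constant predictor for
every kind: several underlying fitters reject zero-variance targets, and the
constant is their exact optimum anyway.

**Hyperparameter search.** `hyperparameter_search()` draws 25 configurations
(layer counts 1–4, units 8–256, conv filters/kernels 2–64, dropout 0–0.4)
with a seeded independent random sampler — simple, reproducible, and
parallel-friendly — scores each by cross-validated MSE, and returns the
argmin with the full trial log. Wall-clock fit+predict times are reported
for orientation only; they are hardware-dependent and never used in any
assertion.

## The two-step anomaly detector

Step 1 standardizes each screened day's MAE against the error population:
`z_p = (ε_p − μ)/σ` with the *population* denominator for σ, flagged when
`z_p > Z = Φ⁻¹(p)` — strictly, one-sided: unusually *small* errors are
normal. With errors fitted and screened on the same population the flag rate
converges to `1 − p` by construction; the default p = 0.925 flags ≈ 7.5% of
days before gating. Guidance: lower p (0.85–0.90) for fragile populations
where small deviations matter, 0.99 for healthy populations where only gross
deviations are of interest.

The reference population is configurable. Fitting μ, σ and the whiskers on
the training subset only (`reference = "train"` in `run_config()`) avoids
test leakage and is the default for the pipeline; passing no reference
windows to `detect_anomalies()` standardizes errors against the screened set
itself (the pooled reading, under which the tail calibration above holds
exactly). The two differ by the model's generalization gap: a train-fitted σ
slightly undershoots on unseen days, inflating the flag rate by a couple of
percentage points.

Step 2 computes, per activity, `Q1` and `Q3` by linear interpolation between
closest order statistics (the type-7 convention — whisker values depend on
this choice, so it is frozen and tested against a hand-rolled oracle) over
all user-days of the reference table, zeros included, and keeps a flagged
day only if at least one activity lies strictly outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`. Ties sit on the normal side of every
threshold: a day exactly at a limit, or exactly at z = Z, is not anomalous.
Whiskers are population-wide (one limit per activity); a per-user variant is
possible by passing a per-user reference table but is not the default, since
single-user quartiles are unstable at realistic day counts. Reports carry
both the calendar date and a per-user ordinal of the screened days, plus the
z-score and each deviated activity with its direction and violated limit.

## Routine clustering

`cluster_routines()` runs seeded k-means on the dedication vectors (raw
percentages by default; a standardized mode divides by per-activity standard
deviations for scale-free distances) and grades partitions by mean silhouette
width under Euclidean distance. `select_k()` sweeps k = 2..10 and keeps the
silhouette maximizer. `k = n` is allowed but degenerate (warned, silhouette
undefined).

## What the simulator emulates — and what it does not

The generator exists so every stage is testable against known ground truth.
It emulates: a dominant sleep block (~31% of the day) with a heavy tail of
small activities; per-user heterogeneity (multiplicative lognormal random
effects, sd 0.15 on the log scale); weekly periodicity (weekday/weekend
multipliers on work and social activities); heterogeneous per-activity
dispersions; and the ≤ 100% day budget. Noise is *logit-normal per activity*
followed by rescaling onto the budget — chosen over a Dirichlet because it
keeps each activity's dispersion independently controllable and leaves
zero-mean activities exactly zero; a Dirichlet couples all variances through
its concentration. Zero noise reproduces the latent means exactly, which the
tests exploit. Defaults mirror a 30-home, ~75-day, 41-activity corpus.

Injected anomalies perturb listed (user, day) targets additively, optionally
conserving the day total by stealing from a donor activity;
`gross_injections()` constructs perturbations that exceed the clean table's
upper whiskers by a margin *and* are large enough in total to spike the
day's MAE, so recovery is guaranteed by construction and recall measures the
detector plumbing, not luck. The event-stream emitter inverts ingest:
episodes realize each day's dedications with `Other_Activity` filling unused
time, and a terminal sentinel event closes the final run; round-trips through
the full ingest pipeline reproduce the table to well under 0.01 percentage
points per cell.

The simulator deliberately does **not** emulate: activity-recognition label
noise (upstream classifiers are ~84–100% accurate, not perfect), missing or
dropped sensor days, long-term drift (seasonal routines, progressive
decline), cross-activity correlation structure beyond the budget constraint,
or within-day ordering (it generates daily totals directly; the event streams
it emits have arbitrary episode order). Passing tests therefore demonstrate
that the machinery is correct and calibrated under known conditions — not
that real populations satisfy the Gaussian error assumption or that the
whisker gate has clinical validity, which require labeled real-world
anomalies.

## Problem sizes and numerical tolerances

The test suite and acceptance script run the full pipeline at the default
synthetic scale (30 users × 75 days × 41 activities ≈ 1,140 training
windows at w = 15) with the short-budget recipe, and gradient checks on
small nets (4–6 units, 4 time steps) where numerical differentiation is
exact enough to resolve 1e-5 relative error. Brute-force oracle comparisons
(z-scores, quartiles, silhouette, column means) are asserted to 1e-9;
duration conservation to 1e-6 s; event-stream round trips to 0.01
percentage points. Calibration of the step-1 flag rate is checked at
n = 100,000 errors within ±0.3 percentage points of the nominal 5% tail.

## Known limitations

* The Gaussian model of MAE errors is an approximation — real error
  distributions are right-skewed, so the effective false-alarm rate can sit
  above `1 − p`; the boxplot gate absorbs part of this.
* Models are population-level by design; they personalize only through the
  window content, not per-user parameters.
* w = 15 (two weeks of context) is the package default; it is a good default
  for weekly-structured routines but should be re-tuned for corpora with
  other periodicities.
* The engine is pure R: ample for the default problem sizes (seconds per
  fit), but not for corpora orders of magnitude larger.
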