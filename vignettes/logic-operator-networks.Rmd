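---
title: "Logic-operator networks for interpretable therapy recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-operator networks for interpretable therapy recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonnrec)
```

## The problem

Clinical decision support for heart-failure therapy faces two linked
obstacles: physicians distrust opaque models, and patient-level data cannot
circulate freely. `lonnrec` addresses both with a pipeline of three parts:

1. **A logic-operator neural network (LONN)** — a feed-forward network whose
   hidden layers are *frozen* perceptrons implementing continuous-valued
   (nilpotent, Łukasiewicz-style) logical operators. Only the first layer
   (which learns a parameter hierarchy over the covariates) and the output
   head are trainable, so the fitted model reads as "a learned weighting of
   inputs, combined through fixed AND/OR gates".
2. **A sequential-regression cohort synthesizer** that replaces a sensitive
   cohort with a fully synthetic one of the same distributional shape,
   with frequency-distribution distance diagnostics.
3. **A dual-model recommender** that trains one network on the whole cohort
   and one on the positive-outcome subset, and flags a binary confidence:
   1 when the two binarized treatment-key predictions agree, 0 otherwise.

## The squashing activation

All logic layers are activated by the squashing function

$$S_\beta(x) = \frac{1}{\beta}\,\ln\frac{1 + e^{\beta x}}
{1 + e^{\beta(x-1)}},\qquad \beta \ne 0,$$

a differentiable approximation of the *cutting function*
$\min(1, \max(0, x))$. Its useful invariances: $S_\beta(0.5) = 0.5$ exactly;
$S_\beta(x) = S_{-\beta}(1-x)$ (a negative slope acts as negation); it is
strictly increasing for $\beta > 0$; and $S_\beta \to$ cutting as
$\beta \to +\infty$ (at $\beta = 100$ the sup-distance is already below
0.01). Its derivative has the closed form
$\mathrm{logistic}(\beta x) - \mathrm{logistic}(\beta(x-1))$, which is what
makes frozen logic gates compatible with backpropagation.

**Numerical form.** We evaluate $S_\beta$ as
$(\mathrm{softplus}(\beta x) - \mathrm{softplus}(\beta(x-1)))/\beta$ with
$\mathrm{softplus}(z) = \max(z,0) + \log(1+e^{-|z|})$: bit-identical in exact
arithmetic, immune to overflow for large $|\beta x|$. At double precision the
mathematically open bounds (0, 1) saturate for $|\beta x| \gtrsim 40$; tests
assert strict interior values only at moderate slopes.

```{r squashing}
squashing(c(0, 0.5, 1), beta = 1.5)
gate_apply(logic_gate("AND", 2), c(1, 1), beta = 50)  # fuzzy "true"
```

## Gates as fixed-weight perceptrons

A unit $S_\beta(w \cdot x + b)$ realizes a nilpotent connective. The 2-input
encodings are AND: $w = (1,1), b = -1$; OR: $w = (1,1), b = 0$; NOT:
$w = -1, b = 1$; NOR: $w = (-1,-1), b = 1$. Other arities follow the family
(conjunction $= \mathrm{cut}(\sum x_i - (k-1))$, disjunction
$= \mathrm{cut}(\sum x_i)$); tests verify every crisp truth table
exhaustively at $\beta = 50$. One published unary row ("NOT(x): 0, 1") is
treated as a typographical artifact — a zero weight yields a constant — and
negation is implemented as the nilpotent $1 - x$.

## The reference architecture

The reference LONN is pinned to the only wiring that reproduces the
published parameter counts (116 trainable, 59 frozen; dense ReLU control:
293 trainable):

| stage | shape | activation | trainable | parameters |
|---|---|---|---|---|
| input layer | 10 → 10 | ELU ($\alpha=1$) | yes | 110 |
| M (hypothesis) layer | 10 → 4 | $S_{\beta_{int}}$ | frozen | 44 |
| AND layer | 4 → 3 | $S_{\beta_{int}}$ | frozen | 15 |
| OR stage | 3 → 2 | $S_{\beta_{int}}$ | fixed wiring | 0 (uncounted) |
| head | 2 → 2 | sigmoid | yes | 6 |

Design choices made where the wiring was genuinely open:

* **M nodes** are described only as frozen "hypothesis groupings with
  different statistical weights". We draw each node's weights once from a
  seeded uniform on $[0,1]$ and normalize them to sum to 1 (bias 0): a fixed
  convex aggregation per hypothesis, fully reproducible from the seed.
* **AND layer** units are the fan-in-4 conjunction gate over all M nodes.
  With identical gates the three AND outputs coincide; the capacity of the
  reference network is deliberately small — that is its selling point — and
  alternative wirings remain constructible through `lonn_spec()`.
* **OR stage** holds fixed unit-weight disjunctions over overlapping windows
  of AND outputs (3 → 2: windows {1,2} and {2,3}); it is parameter-free and
  excluded from counts, which is what makes 116/59 reproducible.
* **$\beta_{int}$** is a per-layer constant (default 1.5), never trained. A
  slope named for the first layer appears in the source material but that
  layer is ELU; no squashing is applied there.
* The dense control is pinned to hidden ReLU widths (10, 10, 4, 3, 2) plus a
  sigmoid head — the only ReLU stack matching 293 parameters.

```{r counts}
count_parameters(build_lonn())
count_parameters(build_dense_baseline())
```

## Training

Mini-batch ADAM (defaults: batch 50, learning rate 0.02, 100 epochs,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on the MSE loss,
reduced as the mean over samples and the two outputs. Gradients flow
*through* the frozen layers — the chain rule uses their fixed weights — but
never update them; tests assert bit-identical frozen parameters after a full
run. The last incomplete mini-batch is used rather than dropped (240
training rows with batch 50 would otherwise lose data). Per-epoch order is
reshuffled from a seed, and identical seeds reproduce identical histories
and weights. The reported *training error* is the mean absolute error on
normalized outputs × 100; the MSE remains the optimization loss.

**Initialization.** Weight initialization is not specified by the reference
material, and the obvious default (Glorot-uniform, zero biases) provably
fails here: the frozen AND block then starts near pre-activation −1.7, where
the squashing derivative is ≈ 0.05, and the narrow (4, 3, 2) ReLU layers of
the control collapse to dead units, freezing its loss at the target
variance. We therefore initialize the LONN's first-layer biases at 1 — which
starts the frozen conjunction block in its responsive region (pre-activation
near 0) — and the ReLU layers of the control with He-uniform weights and
bias 0.1. Deep narrow ReLU stacks remain luck-sensitive; the comparison
protocols use seed replicates for exactly that reason.

## Cohort schema, normalization, and the fixture generator

Cohorts are CSVs over ten covariates (sex, age, creatinine phosphokinase,
ejection fraction, high blood pressure, platelets, serum creatinine, serum
sodium, smoking, anemia), the outcomes `time` (therapy days within a
six-month window) and binary `treatment_key`, and an optional `death` flag.
Binaries pass through as 0/1; continuous variables are min-max normalized.
A published form of the normalization formula contains an evident typo
(a missing `max`); the intended $(x - \min)/(\max - \min)$ is implemented.
Normalization statistics are fitted on the training split only and reused
with clamping — a leakage-free choice; fitting before the split (as the
source material appears to have done) can be emulated by fitting the spec on
the full cohort and passing it to `encode_and_normalize()`.

The fixture generator emulates a heart-failure-like cohort so every stage is
testable without downloads: Bernoulli binaries (sex 0.65, hypertension 0.35,
smoking 0.32, anemia 0.43), truncated-normal age (60 ± 12 on [40, 95]),
log-normal CPK and serum creatinine, truncated-normal platelets and EF — a
two-component mixture (reduced ≈ N(30, 5) w.p. 0.6 vs preserved ≈ N(55, 5))
with the 40% threshold defining systolic heart failure. The treatment key is
the clinically motivated mechanism: probability 0.9 of the SHF-appropriate
class (ACE inhibitor / ARB / beta-blocker, encoded 1) under reduced EF,
0.6 otherwise. Death follows a logistic model in (EF, serum creatinine,
age); therapy time is short for deaths (uniform 4–120 days) and long for
survivors (uniform 60–183). These laws are plausible stand-ins, not claims
about any real registry: a green test establishes that the *machinery*
recovers planted structure, not that the model would reach any particular
accuracy on real EHR data. Real-data features the generator does not
emulate: missingness, coding errors, covariate correlations beyond the
planted ones, informative censoring, and multi-class therapy keys.

Two deliberately configurable corners:

* `sodium_age_slope` (default 0) plants a known linear age → sodium
  coefficient; parameter-recovery tests use it because the default laws are
  otherwise mutually independent in the continuous block.
* `tk_prob_preserved` lowered to 0.1 plants a *separable* mechanism. With
  the default 0.9/0.6 pair, $P(TK = 1 \mid EF) > 0.5$ in both groups, so the
  Bayes classifier is the majority class and no model can beat the majority
  rate in expectation — learnability checks (importance ranking, accuracy
  above majority, LONN-vs-dense tendency) therefore use the separable
  variant.

## Sequential-regression synthesis

`fit_synthesizer()` visits variables in schema order; the first is drawn
from its empirical marginal, each later one from a regression on its
predecessors: logistic for binaries (predictive draw = Bernoulli at the
fitted probability; no posterior uncertainty is modeled), OLS for continuous
variables. The continuous predictive draw (mean + residual-scale normal
noise) is then *norm-rank* back-transformed: draws are replaced by the
original empirical values of matching rank (interpolated empirical quantiles
when the synthetic size differs), so every synthetic marginal reproduces the
observed distribution shape exactly and never leaves the observed range.
Degenerate fits — constant columns, separation, singular designs — fall back
to the marginal model with a message. IDs are freshly randomized.

Quality is scored by the frequency-distribution distance: binary variables
use natural bins, continuous ones 10 equal-width bins over the pooled range;
the distance is the mean absolute relative-frequency difference × 100. On a
fixture cohort of n = 299 with m = 2990 synthetic records the overall mean
distance is ≈ 0.4%, comfortably below the 1% figure reported for the
original pipeline. This metric certifies *marginal* fidelity only; joint
structure is inherited from the regression chain and is not separately
scored, and no formal privacy guarantee is implied by ID randomization.

## The dual-model recommender

`train_pair()` fits the normalization once on the full cohort, trains
`model_full` on every record and `model_positive` on survivors with at least
60 therapy days (`min_time_days`, configurable; "long" is not defined in the
source material and 60 days is one third of the observation window). For a
patient, both models predict; treatment keys are binarized at 0.5. Agreement
yields the full model's prediction with confidence 1; disagreement yields
the positive-outcome model's prediction with confidence 0 and the other
model's prediction attached as the alternative. Matching is defined on the
binarized treatment key only — no time tolerance is defined in the source
material — but `time_tolerance_days` optionally adds one. Source labels
("model 1"/"model 2") are avoided in code because the source material swaps
them between sections; the fields are named `model_full` and
`model_positive`. Every recommendation can be appended to a timestamped
append-only CSV log, with the physician's accept/reject decision when known.

## Evaluation protocols

* `training_error()` — MAE on normalized outputs, percent.
* `classification_metrics()` — accuracy/precision/recall on the positive
  treatment-key class at threshold 0.5; precision is reported as absent
  (`NA`), not zero, when there are no positive predictions.
* `time_rms()` — RMS error of normalized therapy time, percent.
* `beta_sweep()` — fresh default LONNs per (β, seed), 50 epochs, per-β mean
  training error. On fixture data the spread across β ∈ [0.5, 5] stays
  within a few percentage points, matching the reported insensitivity.
* `compare_models()` — dense control vs the 4-M-node LONN vs a widened
  10-M-node LONN (AND/OR stages widened proportionally to 8 and 5) on one
  split. The printed reference metrics for the original (unavailable)
  synthesized cohort are not reproducible here; the suite asserts the
  *tendency* (the control out-trains the LONN in most seed replicates on a
  learnable fixture) instead.
* `input_importance()` — the interpretability claim made operational:
  importance of input $j$ is the column sum of absolute first-layer weights,
  normalized to sum 1; because deeper layers are frozen, this ranking is the
  network's parameter hierarchy. On fixtures whose treatment key depends
  only on ejection fraction, EF reaches the top-3 in at least 7 of 10 seeds.

One reading choice: per-epoch training error under mini-batch ADAM is not
strictly monotone (batch noise produces upticks), so "decreasing over the
first 10 epochs" is asserted as a net decrease over the window.

## Known limitations

* The reference LONN's three identical AND gates collapse to one effective
  logical feature; its accuracy ceiling is low by construction.
* The dense ReLU control occasionally dies (narrow layers) despite the
  He/positive-bias initialization; comparisons are seed-replicated.
* Synthesis models only the regression chain in visit order; reversing the
  order changes conditionals (marginals stay faithful by construction).
* The binary treatment key collapses three drug classes into
  "SHF-appropriate vs alternative"; multi-class keys are out of scope.
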