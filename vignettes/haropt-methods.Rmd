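---
title: "Methods: metaheuristic wrapper feature selection for sensor-based HAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaheuristic wrapper feature selection for sensor-based HAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haropt)
```

## The problem

Sensor-based human activity recognition (HAR) classifies short windows of
body-worn inertial measurements — here six channels, triaxial accelerometer
(m/s²) and triaxial gyroscope (rad/s) sampled at 100 Hz — into activity
classes such as standing, walking, jumping or stair climbing. The KU-HAR
corpus that motivates this package stores 20,750 such windows of 18 classes
in a wide CSV layout (300 sample slots per channel, a class id, a usable
channel length and a serial per row); `read_kuhar_wide()` parses that
dialect and truncates every channel at the declared length, treating
trailing cells as opaque padding.

Rather than feeding raw signals to a deep model, the pipeline summarises
each channel with eight statistics and lets a wrapper search choose, per
classifier, *which* of the resulting 48 features to keep and *how* to tune
the classifier. The contribution implemented here is that wrapper: two
population metaheuristics over a mixed hyperparameter + feature-mask space,
fold-wise optimization with consensus aggregation, a repeated-split
evaluation protocol, and Shapley attribution for the fitted models.

## Feature extraction

For a channel $x_1,\dots,x_n$ the eight statistics are the mean $\mu$, the
median (mean of the two central order statistics for even $n$), the root
mean square $\sqrt{\tfrac1n\sum x_i^2}$, the minimum, the maximum, the
standard deviation $\sqrt{\tfrac1n\sum (x_i-\mu)^2}$, the range
$\max - \min$, and the mean absolute deviation
$\tfrac1n\sum |x_i - \mu|$. Two conventions matter and are deliberate:

* **Population normalisation.** SD and MAD divide by $n$, not $n-1$,
  matching the defining formulas of the feature set. The algebraic identity
  $\mathrm{rms}^2 = \mu^2 + \mathrm{sd}^2$ then holds exactly and is used as
  a property test.
* **Canonical serial order.** The 48 features are ordered channel-major
  (`acc_x`, `acc_y`, `acc_z`, `gyro_x`, `gyro_y`, `gyro_z`), each channel
  contributing mean, median, rms, min, max, std, range, mad. All feature
  indices quoted anywhere in the package are 0-based serials in this order
  (serial 0 = `mean_acc_x`, serial 30 = `range_gyro_x`, serial 47 =
  `mad_gyro_z`), so published fold-wise selections resolve unambiguously.
  The reader/writer pair is the only place where 1-based file columns are
  translated.

## The search space and decoding

A candidate is a 52-vector: four classifier hyperparameters — number of
boosting rounds $P_1 \in [100, 300]$, learning rate $P_2 \in [0.001, 0.2]$,
maximum tree depth $P_3 \in [3, 7]$, minimum child weight
$P_4 \in [1, 10]$ — followed by 48 mask coordinates in $[0, 1]$. The
optimizer dynamics stay fully continuous; only `decode_position()`
discretises, and only at evaluation time:

* integer hyperparameters are rounded to the nearest integer and clamped,
  the learning rate is clamped to its real bounds;
* mask coordinate $d$ selects feature serial $d$ iff it is $\ge 0.5$ — a
  deterministic threshold rather than a stochastic transfer function, so
  equal positions always decode to equal configurations;
* an all-below-threshold mask is repaired by selecting the single largest
  mask coordinate (ties to the lowest serial), which keeps the fitness
  total without penalty terms.

Positions leaving the box after an update are projected back by elementwise
clamping; a non-finite coordinate is replaced by a fresh uniform draw
within its bounds (with a warning), so the search can always continue.

## Golden Jackal Optimization

GJO models a hunting pair: the best (male, $Y_M$) and second-best (female,
$Y_{FM}$) members steer every other member, which plays the prey of its own
update. With prey energy $E = E_1 E_0$, $E_0 = 2r - 1$ ($r \sim U(0,1)$)
and $E_1 = c_1 (1 - t/T)$ decaying linearly over iterations:

* exploration ($|E| \ge 1$):
  $Y_1 = Y_M - E\,\lvert Y_M - R_L \cdot \mathrm{Prey}\rvert$, and
  analogously for $Y_2$ with $Y_{FM}$;
* exploitation ($|E| < 1$):
  $Y_1 = Y_M - E\,\lvert R_L \cdot Y_M - \mathrm{Prey}\rvert$, likewise for
  $Y_2$;

the member then moves to $(Y_1 + Y_2)/2$, clamped, and is replaced only on
strict fitness improvement. $R_L$ is a Lévy-flight vector (Mantegna
construction, stability exponent $\beta = 1.5$, step scale $0.01$), giving
occasional long jumps.

Design choices that the source formulation leaves open, fixed here and
exposed in the configuration: the energy envelope $c_1 = 1.5$ (so both
phases occur early and exploitation dominates late — with $t = 0$,
$\Pr(|E| \ge 1) = 1/3$; at $t = T$, $E_1 = 0$); absolute-value bars around
the distance terms (the original operator); and the Lévy parameters above.

## War Strategy Optimization

Soldiers $P_i$ follow a King (best position) and a Commander (second best
— the formulation names the two roles without defining the Commander, so
second-best is the natural choice). Per soldier and iteration, one of two
moves is chosen by a Bernoulli(0.5) draw (the source lists both without a
selection rule):

* attack: $P_i \leftarrow P_i + 2\rho\,(C - K) + R\,(W_i K - P_i)$,
* defense: $P_i \leftarrow P_i + 2\rho\,(K - P_r) + R\,W_i\,(C - P_i)$,

with $\rho, R \sim U(0,1)$ and $P_r$ a uniformly random soldier. A move is
kept only if the fitness does not decrease ($F_n \ge F_p$); acceptance
promotes the soldier's rank $R_i$ by one and decays its weight
$W_i \leftarrow W_i (1 - R_i/T)^{\alpha}$ with $\alpha = 0.5$ (unspecified
in the source; exposed in the configuration). Rejection leaves position,
rank and weight untouched. After each sweep exactly one soldier — the
current worst — is relocated by the "retraining" rule
$P_w \leftarrow -(1 - R_g)(P_w - \mathrm{median}(P)) + K$ with
$R_g \sim N(0,1)$, the variant its authors call superior; the uniform
random-replacement variant remains available behind
`weak_relocation = "random"`.

Both optimizers are run as maximizers (fitness is a classification score);
minimization is a negation away. The per-iteration trajectory records the
running best, so it is monotone by construction, and the returned solution
attains its maximum.

## The wrapper fitness

`candidate_fitness()` decodes a position, restricts the fold's training
columns to the selected serials, trains the delegated XGBoost classifier
(multiclass softprob; single-threaded histogram method with 64 bins, ample
for smooth window statistics and fully deterministic under a fixed adapter
seed) and returns the **macro F1** score on a held-out evaluation split.

Where that score is computed deserves emphasis, because the protocol's
description leaves it open. Training-set F1 is useless as a fitness — the
classifier interpolates its training data (100% training scores), so every
candidate would score 1.0. Scoring on the fold's 30% test partition would
leak the test set into model selection. The package therefore fixes, per
fold, a stratified 80/20 split *inside* the fold's training partition:
candidates train on the inner 80% and are scored on the inner 20%. The
split is frozen per fold, making the fitness landscape deterministic, and
the adapter seed is fixed at 0 across all calls so fitness differences
reflect the candidate alone. A classifier failure scores 0 with a warning
rather than aborting the search.

## Consensus aggregation

Running the optimization independently per fold yields 10 configurations.
`finalize_config()` consolidates them:

* **hyperparameters** by majority vote — the value occurring most often
  across folds; among tied modes the one whose first occurrence is earliest
  in fold order wins, which subsumes the stated all-distinct fallback
  ("take fold 1's value") as the special case where every count is 1.
  Learning-rate votes compare exact floating-point values; repeats arise
  only from bound clamping (e.g. 0.2), so exactness is the faithful rule.
* **features** by union — every serial selected in at least one fold.
  No frequency threshold is applied.

These two rules reproduce the published finalized configurations from the
published fold tables exactly (23 features and 280/0.116176736/7/1 for the
jackal-optimized model; 44 features and 230/0.2/6/2 for the war-strategy
one), including the modal tie 230-over-211 that the earliest-occurrence
rule resolves.

## Evaluation protocol

The validation scheme is repeated stratified random subsampling: each of
the 10 "folds" is an independent 70/30 train/test split (seeded per fold
from the base seed), not a partition. Splits are stratified via
largest-remainder allocation so the test set has exactly
$\mathrm{round}(0.3\,n)$ rows with per-class counts within one sample of
proportionality — necessary because the application's classes are highly
imbalanced and every class must appear in every test set.

Metrics follow the one-vs-rest conventions: per-class precision, recall
and F from the confusion matrix with 0-when-undefined; macro values are
unweighted per-class means, and macro F is the mean of per-class F scores
(not the harmonic mean of macro precision and recall — the published
summary tables are only consistent with the former). Accuracy is
trace/total. AUC is the midrank Mann–Whitney statistic per class, macro
averaged. Across-fold dispersion uses the sample standard deviation
(ddof = 1), which matches the published dispersion of the reference fold
accuracies to within print rounding, where the population form does not.
Reporting convention is two decimals for percentages and five for AUC;
returned values are never rounded. Wall-clock train/test seconds are
recorded per fold but never asserted — timing is hardware-bound.
`seed_sweep()` repeats the whole scheme under a list of external seeds
(default 5, 10, ..., 50).

## Synthetic data: what it emulates and what it does not

Two generators make every stage testable without the external corpus.

The **signal generator** emulates the corpus structure: windows of six
channels at 100 Hz, default 18 classes. Channel $j$ of a class-$c$ window
is $x(t) = m_{cj} + a_{cj}\sin(2\pi f_{cj} t / 100 + \phi) + \varepsilon_t$
with one uniform phase per window and Gaussian noise. The default model
mirrors the application's class mix: 7 static/transition classes with zero
amplitude and 11 dynamic classes with distinct cadence-range frequencies
(0.8–5.75 Hz), larger accelerometer amplitudes, heavier noise, and gravity
on the accelerometer Z baseline. Baselines are spread deterministically
across classes so window statistics separate them. The generator targets
*statistical structure*, not realism: no inter-subject variability, no
sensor drift or motion artefacts, no realistic spectra. Tests passing on
it show the pipeline's mechanics and contracts are right; they do not
certify real-data accuracy.

The **feature-space benchmark** skips extraction entirely: unit-variance
Gaussian columns, of which `k_informative` randomly chosen ones receive
class-dependent means on an equally spaced grid with adjacent classes
`class_separation` within-class standard deviations apart, the
class-to-grid assignment being a fresh random permutation per column. The
informative serials are recorded in the table's metadata so recovery is
measurable. The default of 6 classes is deliberate: it is the 18-class
application at reduced scale, and — more importantly for a *recovery*
benchmark — with few classes a 2–3-column subset already makes the classes
separable, the wrapper fitness saturates at its ceiling, and mask
coordinates beyond the needed subset lose all selection gradient. Six
classes keep small subsets imperfect, preserving the gradient further into
the informative set.

That plateau effect is also the package's most important known limitation:
at desk scales (hundreds of rows, an inner evaluation split of ~120 rows)
macro F1 reaches 1.0 before the full informative set is needed, so the
*identity* of the best candidate's mask beyond the necessary core is
underdetermined, and neither optimizer — greedy strict-improvement
replacement in GJO, non-degrading acceptance in WARSO — has any pressure
on plateau ties. Full recovery of a planted informative set should
therefore only be expected when the evaluation split is large enough to
resolve the marginal value of every informative column. The test suite
measures enrichment (informative columns are over-represented in selected
masks) rather than pretending full recovery is guaranteed at small n.

## Shapley attribution

Model explanations live in raw margin space, per class: that is the scale
on which the efficiency identity
$f(x) = E[f(x)] + \sum_i \phi_i$ holds exactly for tree ensembles
(probability space would break it through the softmax). Two routes are
provided:

* `exact_shapley()` enumerates all $2^d$ feature subsets (refusing beyond
  $d = 12$) and applies the classical weights
  $|S|!\,(d-|S|-1)!/d!$; a subset's value marginalises absent features by
  averaging the value function over a background set (the interventional
  convention). This is the verifiable oracle: the dummy, symmetry and
  efficiency axioms are asserted on it directly.
* `explain_model()`/`tree_shap()` delegate to the TreeSHAP algorithm built
  into XGBoost (`predcontrib = TRUE`) for the real 23/44-feature models,
  asserting efficiency against the model's margins on every call.

The two routes are tied together by an equivalence test on a toy model
trained on a full $2^8$ factorial design with the design itself as
background: on a factorial training set every tree node's population is a
product set, so TreeSHAP's path-dependent expectations coincide with
interventional background averaging and the routes must agree to float
precision. Rankings use the mean absolute attribution per feature (summed
over classes), ties broken by serial; `explain_instance()` reports the
per-class margin decomposition plus the top signed contributors for the
predicted and (when supplied and different) true class — the template for
misclassification analysis. Background sets for model explanation should
be fixed and seeded; the tests use seeded stratified subsamples so
expected values are reproducible.

## Randomness and determinism

R has no first-class RNG streams, so the package threads explicit seeds
instead of relying on ambient state: every stochastic entry point takes a
seed, runs under an internal `with_seed()` that restores the caller's
`.Random.seed` afterwards, and derives child seeds with
`derive_seed(base, ...)` (a 32-bit mixing function, safe for `set.seed()`
on all platforms). Fold $i$ of a run uses `derive_seed(base_seed, i)`;
its inner split and its optimizer use distinct sub-streams. Identical
seeds therefore give bit-identical fold outcomes, and generator output is
exact across platforms for the integer stream and to double precision for
floats.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script experiments are sized for a single
CPU: sphere benchmarks run the full population 30 × 50 iterations over 10
seeds; wrapper-recovery experiments use the 48-column benchmark at
$n = 600$ with population 15 and 20 epochs over 10 seeds; end-to-end
synthetic pipelines use a few hundred windows with 2–5 folds and reduced
optimizer budgets; evaluation-protocol checks use feature tables of
300–1,800 rows. These are the package's chosen desk-scale study
conditions; the full-scale protocol (population 30, 50 epochs, 10 folds,
20,750 windows) is exactly the same code path with the default
`run_config()` and a real feature table.
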