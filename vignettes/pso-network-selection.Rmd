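---
title: "Selecting network configurations with a particle swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting network configurations with a particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pswarmnet)
```

## The problem and the model

Training a feedforward network by gradient descent requires fixing, before
any gradient is computed, a handful of quantities the gradient cannot reach:
the learning rate, the dropout rate, the momentum coefficient, the
learning-rate decay, and the width of each hidden layer. These interact —
a high learning rate may only work under heavy momentum damping, a wide
layer may only generalize under dropout — so tuning them one at a time is
unreliable, and the objective (held-out score of a trained network) is
noisy, non-differentiable, and expensive.

`pswarmnet` treats the joint configuration as a point in a bounded box of
dimension `4 + L` (four training hyperparameters plus `L` hidden-layer
widths) and searches the box with a particle swarm. Each particle carries a
position and a velocity; at every generation its velocity is pulled toward
its own best position so far (*pbest*) and the swarm's best (*gbest*):

$$V'_i = W V_i + C_1 R_{1,i}\,(pbest_i - X_i) + C_2 R_{2,i}\,(gbest_i - X_i),
\qquad X' = X + V'$$

with $R_1, R_2$ uniform on $[0,1]$ drawn independently per dimension. The
acceleration coefficients and inertia weight follow linear schedules over
the generations $t = 0 \dots t_{\max}$:

$$C_1(t) = C_{1i} + \tfrac{t}{t_{\max}}(C_{1f} - C_{1i}), \quad
  C_2(t) = C_{2i} + \tfrac{t}{t_{\max}}(C_{2f} - C_{2i}), \quad
  W(t) = W_{\max} - \tfrac{t}{t_{\max}}(W_{\max} - W_{\min}).$$

With the default endpoints ($C_1$: 2.5→0.5, $C_2$: 0.5→2.5, $W$: 0.9→0.4)
the swarm begins with strong self-attraction and inertia (broad
exploration) and ends dominated by the social term (local refinement
around the best known configuration).

```{r schedules}
s <- pso_settings(max_iterations = 30)
rbind(t0 = c(w = tviw(0, s), tvac(0, s)),
      t30 = c(w = tviw(30, s), tvac(30, s)))
```

The underlying classifier is a multilayer perceptron written in the
package: tanh (classification) or sigmoid (regression) hidden activations,
a softmax head trained against the mean negative log-likelihood for
classification, and a linear head trained against the mean squared error
for regression. The trainer is plain mini-batch steepest descent with
momentum, per-update learning-rate decay, and inverted dropout; its
analytic gradients are verified against central finite differences in the
test suite to a relative error below 1e-5.

## Fitness: the λ-split protocol

Scoring a particle exactly would mean a full training run per particle per
generation. Instead, the training data is split **once per search** into an
inner training subset (fraction λ, default 0.8, stratified by class) and a
validation subset; each particle is decoded, a fresh network is trained for
a small `eval_epochs` budget with the particle's hyperparameters, and the
validation accuracy (or negated validation MSE) is its fitness. Splitting
once rather than per generation keeps *pbest* scores comparable across
generations — re-splitting would let a particle's recorded best reflect a
lucky split instead of a good configuration. A `training_loss` fitness
variant (negated final training loss, no validation contact) is available
but not the default, because only the held-out score measures what the
search is supposed to optimize.

Every evaluation trains from a fresh initialization; nothing is cached or
warm-started, so a configuration's score never depends on when the swarm
visited it. Per-candidate seeds are derived deterministically from the
master seed, making every search bitwise reproducible.

## From solutions to models

After the last generation the swarm yields one *pbest* per particle and one
*gbest*. Each *pbest* is retrained with the larger `final_epochs` budget on
**all** training data, then scored for ranking on a held-out λ-split of
that same data. The top *h* candidates form the ensemble; prediction is by
majority vote over the members' argmax labels. The *gbest* solution is
retrained the same way and reported separately as the individual model —
the default ensemble contains *pbest* candidates only, which keeps the two
reported models structurally distinct (an ensemble member list and a single
network) rather than letting the individual model also dominate the
ensemble.

Two rules the vote needs that a description of "majority vote" leaves open:
a tie in vote counts is broken by the larger sum of the members' softmax
scores for the tied classes, then by the lower class index; and candidate
ranking ties are broken by the lower candidate index, so selection is
deterministic. For regression, where argmax voting is undefined, the fusion
is the unweighted mean of member outputs (a score-weighted mean is
available as an option).

## What the synthetic generators emulate

`make_classification_data()` produces dense feature matrices min-max scaled
to [0, 1] — the statistical silhouette of pixel data after dividing
intensities by 255 — as Gaussian class clusters whose `separation`
parameter sets the distance of class centers from the origin in noise
standard deviations. Around 4 the task is nearly linearly separable;
test fixtures use 2 where hyperparameter quality should matter and 5 where
a trainer merely has to learn *something*.

`make_qsar_data()` emulates descriptor matrices: a thin latent factor
matrix times sparse loadings plus noise, scaled into the open interval
(0, 1), so the matrix is high-dimensional but PCA-reducible — `pca_reduce()`
recovers ≥ 90% of the variance within `latent_rank + 5` components. The
activity is a quadratic-plus-interaction function of three latent factors,
chosen so that a network with hidden layers can fit it but a linear model
cannot; with zero noise it is exactly recoverable from the true factors,
which the tests use as an oracle.

Neither generator reproduces what makes real benchmarks hard: spatial pixel
correlation, label noise, heavy-tailed descriptor distributions, or
assay-specific activity scales. Passing tests on these fixtures therefore
demonstrates that the machinery is correct and that the search beats an
equal-budget random baseline *under controlled conditions* — not that any
particular accuracy will transfer to real data.

## Numerical choices and degenerate inputs

* **Momentum/decay semantics.** `v ← momentum·v − lr_u·grad`,
  `w ← w + v`, with `lr_u = learning_rate / (1 + decay · u)` and `u`
  counting mini-batch updates from 0 — the legacy SGD rule of the framework
  generation whose hyperparameter ranges (decay around 1e-5–1e-4) the
  defaults use. Decay is a learning-rate schedule here, not an L2 penalty.
* **Dropout placement.** Inverted dropout on hidden activations only,
  during training only: kept units are scaled by 1/(1−p), so prediction
  needs no rescaling and `dropout_rate = 0` reproduces the no-dropout
  trainer bit-for-bit.
* **Initialization.** Weights uniform on (−s, s) with s = 1/√fan_in,
  biases zero, all under a caller-supplied seed. Swarm velocities start at
  zero, so generation 0 is purely the random-position draw.
* **Probability clamping.** Softmax outputs are clamped at 1e-12 before the
  log, so a confident miss costs a large finite penalty instead of `-Inf`.
* **Divergence.** A non-finite mini-batch loss stops training immediately
  and flags the history as diverged; the fitness layer converts that flag
  (and any non-finite score) to `-Inf`, so broken configurations lose
  rankings instead of crashing searches.
* **Velocity cap and clipping.** Velocities are capped at 0.2 of each
  dimension's range (uncapped velocities destabilize narrow boxes such as a
  decay range spanning one order of magnitude); positions are clipped to
  the box and a clipped dimension has its velocity zeroed.
* **Ties in pbest/gbest.** Strict improvement is required; on equality the
  earlier incumbent stays, so a flat fitness landscape leaves the history
  constant.
* **Rounding.** Neuron coordinates stay continuous inside the swarm and are
  rounded half-up, then clipped to the neuron bounds, only when a network
  is built. Zero-width bounds are legal and pin a hyperparameter.
* **Batching.** The last partial mini-batch of an epoch is used as-is, so
  every epoch sees every sample; `epochs = 0` and `learning_rate = 0` are
  exact no-ops.
* **MAPE.** Defined as mean |actual − predicted| / |actual|; zero targets
  are refused unless an explicit epsilon denominator floor is supplied.
* **Uneven folds.** In k-fold splitting the first `n mod k` folds receive
  one extra record, applied within each class for stratified splits.

## Design decisions that were genuinely open

* **The update equations.** The canonical velocity/position updates above
  are used. Printed variants that update the position from *pbest* rather
  than from the current position, or that mix generation indices within one
  update, are internally inconsistent with the standard swarm literature
  and were not implemented.
* **Equal budget.** The random baseline draws the same number of candidate
  configurations as the swarm has particles, and both arms train their
  candidates with identical epoch budgets; the swarm additionally spends
  its search budget. This mirrors how a practitioner would actually use the
  baseline (train k random configurations, keep the best) and makes the
  comparison "search versus no search at the candidate level".
* **Depth is fixed per experiment.** The number of hidden layers is a
  constant of the search space, not a searched dimension; depth sweeps are
  run as separate experiments with different spaces.
* **PCA target dimension.** When no component count is given,
  `pca_reduce()` keeps the smallest number of components explaining 95% of
  the variance.

## Problem sizes

The package's own test and demonstration sizes are desk scale by design:
classification fixtures of 100–400 samples with 4–15 features, descriptor
fixtures of about 100–200 × 30–60 with latent rank 3–10, swarms of 4–20
particles over 2–30 generations, and evaluation budgets of 2–5 epochs
(final budgets 3–20). The comparison properties (swarm ≥ random baseline;
ensemble ≥ median member, each in at least 8 of 10 seeds) are asserted at
population 8, 10 generations, 3 evaluation epochs on 300-sample fixtures.
These sizes are large enough for the qualitative behavior to be stable
across seeds while keeping a full suite run around half a minute.

## Known limitations

* The trainer is dense, single-threaded R; it is built for correctness and
  reproducibility at desk scale, not for ImageNet-scale throughput.
* Only tanh/sigmoid hidden units and softmax/linear heads are provided; no
  convolutional or recurrent layers, batch normalization, or second-order
  optimizers.
* The swarm assumes a box-bounded, fixed-dimension search space; it cannot
  search over depth, activation choice, batch size, or epochs.
* Fitness noise from short training runs is handled only by the swarm's
  own averaging behavior; no repeated-evaluation or racing scheme is
  implemented.
* The IDX reader loads the whole array into memory; files larger than
  memory are out of scope.
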