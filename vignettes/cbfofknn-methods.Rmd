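---
title: "Tuned fuzzy k-NN by bacterial foraging: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuned fuzzy k-NN by bacterial foraging: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfofknn)
```

This vignette is the package's own account of the statistics it implements:
the fuzzy classifier, the optimizer that tunes it, the nested evaluation
design, the synthetic data that makes all of it testable offline, and the
numerical decisions taken where the underlying method family leaves them
open.

## The classifier

`fknn()` implements fuzzy k-nearest neighbours with constrained (Keller)
training memberships. Each training pattern receives membership
$0.51 + 0.49\,n_{own}/K$ in its own class and $0.49\,n_j/K$ in every other
class $j$, where the $n_j$ count the pattern's $K$ nearest training
neighbours by Euclidean distance, the pattern itself excluded. The 0.51
floor guarantees each pattern leans towards its observed label while the
neighbour counts encode how deep it sits inside its class; rows sum to one
by construction. Prediction averages the membership rows of the query's $k$
nearest training patterns with weights
$w_j = \lVert x - x_j\rVert^{-2/(m-1)}$ and takes the argmax.

Assumptions worth keeping in mind: Euclidean distance on features scaled to
a common range (the pipeline min-max scales to $[0,1]$ first), and a
meaningful local neighbourhood structure — the method has no notion of
feature relevance, so uninformative features dilute distances.

Numerical decisions:

* **Zero distances.** The weight $w_j$ diverges as a distance tends to 0.
  If any of the $k$ neighbours lies within $10^{-6}$ of the query (squared
  distance $10^{-12}$), the prediction is the plain average of the
  membership rows of those coincident neighbours — the continuous limit of
  the weighted vote.
* **Ties.** Neighbour ties at the $k$-th distance are broken by training
  index (stable sort), and class ties at the argmax by the lower class
  index; both make predictions deterministic.
* **Membership $K$.** The same symbol serves as membership-construction and
  prediction neighbourhood size in the method family; the package follows
  that and sets `k_init = min(k, n - 1)` unless told otherwise. Prediction
  may use up to $k = n$ neighbours; membership construction is capped at
  $n-1$ because the pattern itself is excluded.
* **Fuzzy strength.** $m \to 1$ recovers the nearest-neighbour rule
  (weights concentrate), $m \to \infty$ the unweighted $k$-mean; the tuning
  box $(1, 10]$ is clamped below at $1.01$, which already yields a weight
  exponent of 200 — effectively the 1-NN limit at double precision.

## The optimizer

`cbfo()` is a bacterial foraging optimizer over a box. Per chemotaxis pass
each bacterium tumbles in a random unit direction, moves one step of length
$C(i) \times \mathrm{range}_d$ per dimension, and swims up to $N_s$ further
steps while the cost keeps improving; positions are clamped to the box.
After $N_c$ passes the healthier half of the swarm (lowest accumulated
cost, ties by index) replaces the weaker half; after $N_{re}$ such blocks
each bacterium is redispersed uniformly with probability $P_{ed}$. Two
enhancements define the "C" variant:

* **Chaotic initialization.** A logistic-map trajectory
  ($x_{t+1} = 4x_t(1-x_t)$, start value uniform in $(0,1)$ avoiding the
  fixed/periodic points 0.25, 0.5, 0.75) supplies the raw $(0,1)$
  coordinates, mapped affinely onto the bounds. The map is interpreted as a
  coordinate *generator* rather than a multiplier of a uniform population:
  multiplying positions by chaotic values would only shrink the swarm
  toward the lower bound, whereas a space-filling start is what an
  ergodic sequence is for. Note the consequence: all $S \times d$
  coordinates come from one trajectory, so the initial swarm lies on a
  one-dimensional manifold of the box; dispersal and chemotaxis provide
  the remaining exploration.
* **Gaussian mutation of the incumbent best.** Once per pass the best point
  is perturbed by a zero-mean Gaussian with per-dimension standard
  deviation $\sigma \times \mathrm{range}_d$ and the proposal is accepted
  only if strictly better. The mutation variance is a free parameter of the
  method family; this package starts it at `sigma = 0.1` and lets it
  self-adapt by the classical 1/5-success rule (multiply by 1.5 on
  success, by $1.5^{-1/4}$ on failure, floored at $10^{-12}$). A constant
  scale either stalls exploitation (large $\sigma$) or loses its basin-escape
  role (small $\sigma$); the adaptive scale gives the expected log-linear
  local convergence on smooth objectives while the swarm machinery handles
  exploration. `sigma = 0` disables mutation entirely, and
  `chaos = FALSE, mutation = FALSE` is plain BFO.

Other choices: out-of-bounds moves are clamped (feasibility preserved, no
rejected evaluations); the classical cell-to-cell attract/repel swarming
term is implemented but off by default since its constants are not part of
the tuned method; the best-so-far record is updated by every evaluation,
so the reported convergence curve is non-increasing and ends at the
returned value. A fixed seed threads one RNG stream through
initialization, tumbles, mutation and dispersal, making whole runs
bit-reproducible.

Default budgets: `cbfo_control()` is the hyperparameter-tuning profile
(S = 8, $N_c$ = 25, $N_s$ = 4, $N_{re}$ = 3, $N_{ed}$ = 2, $P_{ed}$ = 0.25,
$C(i)$ = 0.1). `cbfo_benchmark_control()` is the function-optimization
profile: population 50 with 500 total passes, realised as
$N_{ed} \times N_{re} \times N_c = 2 \times 5 \times 50$ so that both
reproduction and dispersal fire several times within the stated iteration
total. The step fraction $C(i)$ defaults to 0.1 everywhere; 0.2 is the
documented alternative for harder, noisier tables and is a single control
argument away.

## The tuning pipeline

`nested_cv()` estimates generalization with stratified outer folds
(default 10) and tunes $(k, m)$ with stratified inner folds (default 5)
inside each outer training split. The optimizer works on a continuous 2-D
box; `decode_position()` rounds the first coordinate to an integer
$k \in [1, \min(50, n-1)]$ and clamps the second to $m \in [1.01, 10]$.
The inner objective is the mean inner-fold error rate of the decoded pair.
Three design points matter:

* **Leakage control.** Min-max scaling is fitted on the outer training
  split only and applied unchanged to the held-out fold (whose values may
  leave $[0,1]$); the held-out indices never reach the inner objective.
  The fitted object records the per-fold index sets so tests can assert
  this mechanically.
* **Fixed inner folds.** The inner fold assignment is drawn once per outer
  fold, so the tuning objective is deterministic during the search — the
  optimizer compares parameter pairs on identical splits. Distances and
  neighbour orderings per inner split are precomputed once
  (they do not depend on $(k,m)$), which makes each objective evaluation a
  table lookup; the cached path is tested equal to the plain
  `inner_fitness()`.
* **Scoring.** AUC needs a continuous score; the positive-class fuzzy
  membership is the natural one and is what `nested_cv()` ranks. AUC is the
  midrank Mann–Whitney statistic, so tied memberships count half. Reported
  ACC/sensitivity/specificity are percentages; AUC stays in $[0,1]$.

Statistical comparison of optimizer runs goes through the two-sided
Wilcoxon rank-sum test (`rank_sum_test()`), exact by enumeration for
combined samples of at most 12 without ties and the tie-corrected normal
approximation otherwise.

## The synthetic generator

Real sustained-phonation tables cannot be redistributed with the package,
so `generate_dataset()` emulates their shape: class-conditional Gaussians
with features in equicorrelated blocks (a shared-factor construction:
$x = \sqrt{\rho}\,z_0 + \sqrt{1-\rho}\,z$), a standardized mean shift
`effect_size` on the informative features, and presets matching the two
motivating datasets' sample structure — `oxford_like()` (147 patients / 48
controls, 22 features) and `istanbul_like()` (192 / 96, 26 features). The
default within-block correlation of 0.6 in blocks of 4–5 mirrors the
strongly collinear jitter and shimmer families; the default effect size of
1 makes the problem learnable but not trivial.

What the generator does *not* emulate: repeated recordings nested within
subjects (an optional concern the per-sample CV design deliberately
ignores, matching the evaluation protocol it reproduces), heavy-tailed and
skewed marginals of real perturbation measures, and label noise. Passing
tests on this generator therefore demonstrate correctness of the
machinery and sane behaviour under controllable separation — not clinical
performance. The pipeline-level checks use `effect_size = 3`, where a
correct implementation should sit at or near ceiling accuracy, and
`effect_size = 0`, where it should sit at chance.

## Problem sizes in the test suite

The suite favours many small seeded problems over few large ones: oracle
equivalence is enumerated on training sets of at most 12 points (200
random trials); optimizer invariants run on ~100 randomized miniature
configurations; distributional checks on the generator use $10^4$ samples
at 3-standard-error tolerances; the benchmark-average checks run the full
30-seed protocol on the five fixed-dimension functions (about half a
minute); the nested-CV checks use the full 195-sample preset with the
standard tuning profile. Everything is deterministic given the seeds
embedded in the tests.

## Known limitations

* The fixed-step chemotaxis walk cannot refine below its step length;
  final-digit convergence on smooth problems is delivered by the adaptive
  mutation, so switching mutation off (`mutation = FALSE`) trades accuracy
  for a purer ablation of the base algorithm.
* On multimodal objectives with competing basins (e.g. the 6-D Hartmann
  function) the greedy mutation polishes whichever basin the swarm found;
  run-to-run dispersion across seeds reflects basin choice, not numerical
  noise.
* The classifier stores its full training set and computes dense distance
  matrices; the intended regime is hundreds of samples, not tens of
  thousands.
* `stratified_folds()` stratifies by class only; grouped sampling designs
  (multiple recordings per subject) need group-aware folds before the
  reported CV numbers can be read as subject-level generalization.
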