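---
title: "Modeling drug solubility in supercritical CO2: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug solubility in supercritical CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfsol)
```

## The problem

Supercritical CO2 is a green solvent for micronizing poorly water-soluble
drugs; process design hinges on how much drug the fluid dissolves at a given
temperature and pressure. The package correlates the mole-fraction solubility
of ketoprofen in supercritical CO2 with temperature `T` (K) and pressure `P`
(bar), using the bundled 28-point isothermal table (4 temperatures from
308.15 to 338.15 K crossed with 7 pressures from 160 to 400 bar). The data
show two robust qualitative features: solubility grows roughly exponentially
with `T` and roughly linearly with `P`, and the solubility distribution is
right-skewed (values span 2.21e-5 to 7.12e-4).

Three regression families are compared, each tuned by a Water Cycle
Algorithm (WCA) metaheuristic minimizing cross-validated RMSE and filtered
by AIC:

* **PPR** — piecewise polynomial regression on a CART-like axis-aligned
  partition of the (scaled) `T x P` box;
* **KRR** — kernel ridge regression with a radial basis kernel, solved in
  closed form in the dual;
* **TDR** — a Tweedie generalized linear model with power variance
  `Var(Y) = phi * mu^p` and log link, fitted by quasi-likelihood IRLS.

## Data handling

Only the features are standardized (mean 0, spread 1 on the fitting data);
the target stays on its raw mole-fraction scale, so reported MSE (~1e-9) and
MAE (~1e-5) magnitudes are directly comparable with published benchmark
values for this dataset. Train/test splits are random 80/20 with the test
size fixed by round-half-up (`n = 28` gives 22/6). Because the original
benchmark's split seed is unreported, the reproduction protocol is defined
over ten documented split seeds (1--10): the headline value is the best
test-set metric across those seeds and the median is reported alongside.

## Piecewise polynomial regression

Each segment carries a full total-degree-`d` polynomial in the two scaled
features (`(d+1)(d+2)/2` coefficients, `d` tunable in 1--3), fitted
independently by OLS — no continuity constraint is imposed at segment
boundaries, consistent with the CART-style framing. The partition is grown
greedily: candidate splits are midpoints between consecutive sorted unique
training coordinates on either axis, a split is accepted only if it
decreases the penalized criterion

```
RSS + penalty_weight * n_parameters
```

and growth stops at `max_segments`, when no split helps, or when a child
would hold fewer points than coefficients. The penalty weight is tuned on a
log10 scale over [1e-16, 1e-2], wide enough to bracket the raw-scale RSS of
this data. Ties are broken deterministically (earlier leaf, temperature axis
first, lower split coordinate); query points on a boundary belong to the
upper segment, and out-of-box queries are clipped to the training box.

## Kernel ridge regression

The estimator minimizes mean squared error plus a squared RKHS-norm penalty;
its dual solution solves `(K + lambda*N*I) alpha = y` with
`K_ij = exp(-gamma * ||x_i - x_j||^2)`. Both `lambda` (1e-8 to 1) and
`gamma` (1e-2 to 1e2) are tuned on the log10 scale; the ranges are natural
for standardized features, where squared distances are O(1). The smoother
trace `trace(K (K + lambda*N*I)^-1)` serves as the effective parameter count
in AIC. The solve is by Cholesky and its residual is checked against a 1e-8
relative tolerance.

## Tweedie regression

The power-variance family interpolates between Poisson-like (p near 1) and
gamma (p = 2) behavior; p in (1, 2] suits strictly positive right-skewed
responses. With a log link, IRLS uses working response
`z = eta + (y - mu)/mu` and weights `mu^(2-p)`; convergence is declared at a
relative coefficient change below 1e-10 (at most 100 iterations), and the
dispersion is the mean squared Pearson residual over `n - q`. The tuned
power ranges over [1.1, 2]; an optional ridge term on the non-intercept
coefficients (log10 scale, down to an effectively inactive 1e-12) guards
near-collinear designs. At p = 2 the fit coincides with a gamma GLM, which
the tests exploit as an independent oracle.

## The Water Cycle Algorithm

Candidate hyperparameter vectors are raindrops in a box-bounded search space
(continuous, optionally log10-scaled; integer; categorical — the latter two
relaxed to continuous coordinates and repaired by rounding/nearest index,
with out-of-bounds positions clipped). After uniform initialization the best
drop is the sea, the next `N_sr - 1` are rivers, and the remaining drops are
streams allocated to the sea/rivers in proportion to cost-derived intensity.
Each iteration: streams flow to their river and rivers to the sea by
`X_new = X + U(0, 2) * (X_target - X)`; a drop that beats its target
exchanges roles with it, and the sea always ends the step holding the
population minimum. Rivers (and sea-bound streams) that approach the sea
within `d_max` evaporate and rain back as fresh uniform samples; `d_max`
decays linearly from its initial value to zero across the iteration budget,
so restarts fade out as the search narrows. The whole run is deterministic
given one seed.

Design notes made where the method description left choices open: moves are
accepted unconditionally (the canonical formulation) with elitism enforced
at the sea; the decay of `d_max` is linear to zero, which makes the
evaporation mechanism vanish exactly at the end of the budget; the objective
is *minimized* validation RMSE. Standalone optimizer defaults are population
30, `N_sr` 4, `d_max` 0.1 (in range-normalized coordinates), 200 iterations.
The tuning pipeline overrides the budget to population 12 and 25 iterations
(~300 objective evaluations): the family search spaces have only 2--3
dimensions, and in repeated runs the cross-validated RMSE surface is already
well explored at that budget.

## Tuning protocol and AIC filter

The tuner's objective is the RMSE of pooled out-of-fold predictions under
5-fold cross-validation on the training subset (plain training RMSE would
reward interpolation); fold assignment is seeded and fixed across objective
evaluations so the objective is deterministic. After the WCA run, the five
best distinct candidates of the final population are refitted on the full
training subset and the one with the least `AIC = n*log(MSE) + 2k` is kept
(`k`: total polynomial coefficients for PPR, smoother trace for KRR,
coefficients plus one for the dispersion for TDR). This Gaussian-residual
AIC form is the standard choice when the criterion is invoked without a
likelihood.

## The synthetic generator

The generator emulates the two stated trends with the simplest separable
surface,

```
y(T, P) = base * (1 + pressure_slope * (P - P0)) * exp(temp_rate * (T - T0)),
```

defaulting to the lower grid corner as reference (T0 = 308.15 K,
P0 = 160 bar) and to coefficients of the magnitude recovered from the real
table (`base = 2.21e-5`, `temp_rate = 0.065` per K, `pressure_slope = 0.004`
per bar). Noise is multiplicative lognormal with log-scale sigma 0.05 — a
typical relative scatter for solubility measurements — which preserves
positivity and right-skew; sigma = 0 returns the exact surface. An optional
`T x P` interaction coefficient exists but defaults to zero: whether the
real data's interaction exceeds the separable form's capacity cannot be
decided from 28 points. What the generator does *not* emulate: systematic
measurement bias, pressure-dependent error structure, or any physical
(density-based) solubility model — so passing recovery tests shows the
pipeline's statistical machinery works, not that the surface family is
physically true.

Surface parameters are recovered by log-scale nonlinear least squares
(Levenberg-Marquardt, seeded by the linearized regression); the model
function is exactly the generator's, so noiseless data identify the
parameters to numerical precision.

## Problem sizes in the test suite

The suite exercises the full pipeline at the study's own scale: the
benchmark reproduction runs all three families over the ten documented
split seeds on the 28-row table; optimizer convergence uses the standalone
defaults (population 30, 200 iterations, 20 seeds); parameter recovery and
the permuted-target overfit guard use 20 replicates each, the latter with a
reduced tuner budget (population 8, 6 iterations) that is still ample for
the 2--3-dimensional spaces.

## Known limitations and observed deviations

* With a clean best-of-ten-seeds protocol, all three families exceed their
  published single-split test metrics; in particular the Tweedie model's
  best test R^2 (~0.98 in our runs) is far above the published 0.84, and the
  kernel ridge median edges slightly ahead of the piecewise model's median
  (~0.984 vs ~0.980, consistently across tuner seeds). The published
  PPR > KRR > TDR ranking therefore reproduces for the gap to TDR but not
  robustly for PPR vs KRR; the corresponding acceptance checks are left
  asserting the published ordering and fail honestly.
* Six held-out points make test metrics extremely seed-variable; best-of-ten
  values are optimistically biased by construction, which is why medians are
  always reported alongside.
* `R^2` on zero-variance observations is undefined and returned as `NA`
  with a warning (MSE/MAE are still computed).
* The AIC filter compares only near-optimal CV candidates; with raw
  mole-fraction targets the `n*log(MSE)` term dominates `2k`, so the filter
  breaks ties toward parsimony rather than overriding cross-validation.
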