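---
title: "Hybrid self-adaptive sine cosine tuning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid self-adaptive sine cosine tuning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsasca)
```

## The problem

Benzo(a)pyrene (B[a]P) is a carcinogenic five-ring polycyclic aromatic
hydrocarbon used as the regulatory indicator of carcinogenic PAH exposure.
Its daily ambient concentration at a monitoring site is driven by a
nonlinear mix of co-emitted pollutants (particulate matter and its trace
constituents, nitrogen and sulfur oxides) and meteorology (temperature,
boundary-layer height, humidity, precipitation), with pronounced
cold-season peaks when heating emissions rise and atmospheric removal
slows. A gradient-boosted regression-tree model can capture this
relationship, but its predictive quality depends strongly on
hyperparameters, and hyperparameter selection is itself a hard global
optimization problem. This package treats that selection as a continuous
box-bounded minimization and solves it with swarm metaheuristics: the sine
cosine algorithm (SCA), the firefly algorithm (FA), and a hybrid
self-adaptive SCA (HSA-SCA) that switches from sine-cosine exploration to
firefly exploitation late in the run. The tuned model is then interpreted
with Shapley attributions, including per-prediction *relative* shares.

## The optimizers

All three optimizers minimize an arbitrary objective over a
[search_space()] of box bounds (continuous or integer dimensions), keep an
elitist destination point `P*` (the best solution ever evaluated), and
evaluate the whole population once per iteration, so a run with population
`n` and `maxIter` iterations costs `n * (maxIter + 1)` objective
evaluations.

**Sine cosine update.** Per component, with fresh random draws,

    x' = x + r1 * sin(r2) * |r3 * P* - x|   if r4 < 0.5
    x' = x + r1 * cos(r2) * |r3 * P* - x|   otherwise

with `r1 = a - t * a / maxIter` (amplitude `a = 2`, shrinking linearly so
early iterations explore and late ones exploit), `r2 ~ U(0, 2*pi)`,
`r3 ~ U(0, 2)`, `r4 ~ U(0, 1)`. The `r1` schedule and the `r2`–`r4`
distributions follow the original SCA formulation; the hybrid's source
description leaves them open, so they are fixed here once and exposed in
`sca_control()`.

**Firefly update.** A solution moves towards a brighter (fitter) one:

    x' = x_i + beta0 * exp(-gamma * r_ij^2) * (x_j - x_i) + alpha_t * (kappa - 0.5)

with `kappa` a per-component Gaussian draw and `alpha_t = alpha0 *
alpha_decay^t`. Both the distance `r_ij` and the walk term operate on the
range-normalized scale: coordinate differences are divided by each
dimension's width before the distance is squared, and the walk is
multiplied by the width. Without this, one `gamma` cannot serve spaces of
different units — on a wide box the attraction term
`exp(-gamma * r^2)` underflows and the firefly move degenerates into an
isotropic random walk, which measurably hurt the hybrid in our sphere
benchmarks. The defaults `beta0 = 1`, `gamma = 1`, `alpha0 = 0.25`,
`alpha_decay = 0.9` were chosen on that normalized scale (classical
firefly defaults assume unit-scale problems) and are exposed in
`fa_control()`.

**Hybrid control.** For iterations `t < vs` (default
`vs = ceiling(maxIter / 5)`, so at least one pure iteration survives any
`maxIter`) every solution takes the sine-cosine move. From `t >= vs`, each
solution draws `rnd ~ U(0, 1)` and moves by sine-cosine when `rnd < sm`,
otherwise by a firefly step attracted to `P*`. The search-mode probability
starts at `sm = 0.8` and loses a tenth of its value
(`decay_sm()`: `sm - sm/10`) once per hybrid iteration, i.e.
`sm = 0.8 * 0.9^k` after `k` hybrid iterations, handing the late search
over to exploitation. Two points were genuinely open and are decided here:
the decay clock starts at `t = vs` (not at 0), matching the intent of a
stronger firefly emphasis only "in the latter rounds"; and the hybrid's
firefly move attracts towards the destination `P*` rather than sweeping
all pairs, because the hybrid schedule grants each solution exactly one
move per iteration. The standalone `run_fa()` keeps the classical pairwise
sweep, in which brightness is judged by the fitness snapshot taken at the
start of the iteration and the brightest firefly performs a pure random
walk.

**A note on random-stream design.** The engine consumes one uniform
mode-gate draw per solution per iteration in *both* `run_sca()` and
`run_hsa_sca()`; pure-SCA phases simply ignore it. This makes "hybrid with
the hybrid phase disabled" (either `vs = maxIter` or `sm` pinned at 1)
reproduce the pure SCA trajectory draw for draw under a shared seed — a
property the test suite checks identically, and a useful guarantee when
attributing performance differences to the hybrid phase alone.

**Degenerate inputs.** Proposals are repaired by clamping to the box;
integer dimensions round half-up (`floor(x + 0.5)`) so repairs do not
depend on parity, then clamp. Objectives returning non-finite values are
recorded as `+Inf` fitness with a warning and can never become the
destination, so a single pathological configuration cannot crash or win a
run. The destination is strictly elitist; convergence series are therefore
monotone non-increasing by construction.

## The tuning harness

Six booster hyperparameters are searched, with the bounds

| dimension | bounds | kind |
|---|---|---|
| `eta` (learning rate) | [0.1, 0.9] | continuous |
| `min_child_weight` | [1, 10] | continuous |
| `subsample` | [0.01, 1] | continuous |
| `colsample_bytree` | [0.01, 1] | continuous |
| `max_depth` | [3, 10] | integer |
| `gamma` (split loss) | [0, 0.8] | continuous |

Fitness is the mean squared error of the trained booster on the held-out
test partition (a config switch allows training-partition fitness, but
held-out MSE is the default and the quantity the summaries report). The
data split is a seeded random 70/30 row partition with
`floor(n * fraction)` training rows — for a 645-row campaign, 451 train
and 194 test — shared by every optimizer in a comparison. The regression
objective is squared error throughout; all remaining backend settings stay
at their defaults except the ensemble size, fixed at 30 boosting rounds,
single-threaded. Thirty rounds is the package's problem-size choice: with
daily campaigns of a few hundred rows and learning rates bounded below at
0.1, the fit quality plateaus well before 100 rounds while the multi-run
protocol's cost scales linearly in rounds. The backend RNG is seeded from
the problem seed on every training call (saving and restoring the outer
RNG state), so a fitness evaluation is a deterministic function of
(position, problem) and re-fitting the best configuration reproduces the
best fitness exactly. Feature columns are ordered by name inside the
problem object, making fitness invariant to the column order of the input
table. No feature scaling is applied — tree ensembles are invariant to
monotone feature scaling, and the original measured units are kept for
interpretability.

Evaluation metrics follow the standard definitions: MSE, RMSE, MAE, R²,
Pearson R, and Willmott's index of agreement

    IA = 1 - sum((a - a_hat)^2) / sum((|a_hat - a_bar| + |a - a_bar|)^2)

with `a_bar` the observed mean. IA is bounded in [0, 1], equals 1 only for
a perfect prediction and 0 for the mean-constant prediction.

## The comparison protocol

`run_experiment()` runs each named optimizer `n_runs` times (study
defaults: 20 runs, population 40, 20 iterations) on the *same* problem
object; run `k` of every algorithm uses seed `base_seed + k`, so runs are
paired across algorithms by index — the pairing key for the paired-t test.
Per-algorithm summaries report best, worst, mean, median, standard
deviation and variance of the best-per-run fitness, with the sample
(n − 1) convention for std/var since a population convention is equally
defensible and the choice must be stated for reproducibility.

The significance chain is: Levene's test (one pooled k-group test,
median-centred) for homoscedasticity; Shapiro–Wilk per algorithm for
normality; then, per contender, a Shapiro–Wilk pre-check on the *absolute*
paired differences followed by the paired-t test on the *signed*
differences. Running the normality pre-check on absolute rather than
signed differences is deliberate, mirroring the protocol this package
operationalizes; when the pre-check fails at the 0.05 threshold the
comparison still reports both numbers but warns that the t p-value may be
unreliable. Contender algorithms beyond the built-in three can be added
through `register_optimizer()` without touching the protocol.

## Shapley interpretation

Attributions come from the backend's TreeSHAP implementation —
tree-path-dependent expectations, which need no background sample and
match the cited explainer usage; attributions are computed over the full
dataset by default since interpretation concerns all observations. Local
accuracy (base value plus row attributions equals the prediction, within
`1e-6 * max(1, |prediction|)`) is verified on every call and enforced with
an error. The *relative* attribution of feature f in prediction i is
`|phi(i,f)| / sum_g |phi(i,g)|` — each row of shares sums to 1. Because
that definition is per-prediction, the aggregate percentage reported per
feature is the *mean of the per-prediction shares*; the alternative
aggregate (each feature's share of summed mean-absolute values) is also
exported, as the two can differ when heavy-tailed predictions concentrate
attribution.

## The synthetic generator

The generator emulates the statistical structure of a two-year suburban
monitoring campaign so the whole pipeline is testable without the original
records: 645 consecutive daily rows; an annual cycle with cold-season
pollution (winter temperature minima, shallow boundary layers, elevated
PM10, As, Cd, Pb, SO2, NOx); internally correlated meteorology (surface
and 2 m temperature share the seasonal signal, with enough independent
scatter that the two remain distinguishable to an attribution method); and
a lognormal-tailed target. The target is built from the *realized* feature
columns: standardized (against fixed reference constants, not sample
statistics) log-scale drivers with declared effect sizes — low surface
temperature 0.6, arsenic 0.35, PM10 0.22, NOx 0.12, plus a 0.15
cold-temperature × PM10 interaction — exponentiated and multiplied by
lognormal noise (sigma 0.35), clipped at zero. With these defaults the
target's median sits near 1 ng/m³ and its max/median ratio lands in the
10–40 range across seeds, echoing wintertime B[a]P campaigns where annual
maxima reach the tens of ng/m³ against medians near 1; the values
deliberately do not chase any particular campaign's numbers. Fixed
reference standardization means `noise_sigma = 0` makes the target an
exact function of the features, which the tests exploit.

What the generator does *not* emulate: measurement error and detection
limits, missing days, autocorrelated synoptic episodes, long-range
transport events, or the undefined assimilation-system covariates (MOFI,
LIB4/LIDS, SHIF, LHTF, CAPE are generated as generic seasonal covariates
only). Passing the recovery tests therefore shows the pipeline works on
data with this seasonal, collinear, heavy-tailed structure — not that it
would reproduce any specific field campaign.

## Problem sizes in the test suite

The suite exercises the full protocol at reduced scale chosen to keep a
complete run in minutes on one core: the headline-ordering regression uses
the default 645-row dataset with 10 runs, population 20 and 10 iterations
per algorithm; end-to-end recovery tunes with population 10 over 8
iterations and then checks top-driver recovery across 20 generator seeds;
statistical calibration uses 500 null and 200 shifted replicates of 20
paired runs. Unit tests use 60–200-row datasets and 8–20 boosting rounds.

## Known limitations

- Box constraints only; no constraint handling beyond clamping, and no
  multi-objective support.
- The contender metaheuristics of the wider comparison (GA, PSO, ABC, WOA,
  HHO, ChOA) are not re-implemented; the registry accepts external
  implementations with the same calling convention.
- The paired-t chain assumes near-normal run distributions;
  non-parametric fallbacks (Wilcoxon, Friedman) are out of scope.
- TreeSHAP attributions are tree-path-dependent; interventional
  attributions against a reference sample are not provided.
- With strongly collinear drivers (e.g. two temperatures sharing a
  seasonal signal), attribution mass can split between proxies; the
  generator keeps enough independent scatter for the declared ordering to
  be recoverable, but real campaigns may not.
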