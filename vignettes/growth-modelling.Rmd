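---
title: "Modelling multi-substrate bacterial growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-substrate bacterial growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cybgrowth)
```

`cybgrowth` asks a question that comes up whenever a bacterium faces a
mixture of carbon sources: is the observed order of nutrient consumption
"just kinetics" — different uptake rates acting independently — or the
signature of active regulation that allocates the cell's enzymatic capacity
to the most profitable substrate? The package formalizes the question as a
model comparison between an unregulated Michaelis–Menten–Monod (MMM) model
and a cybernetic model with optimality-derived control variables, fitted to
the same multi-pool batch-culture data and scored per species by Pearson
correlation and AIC. Everything runs on synthetic data that emulates a
defined-medium experiment: 19 amino acids, 0.2 mM each, falling into four
co-utilized kinetic groups whose sequential exhaustion produces a triauxic
biomass curve.

## The two growth models

Both models track biomass $\phi P$ (an OD600-equivalent) and four lumped
substrate pools $\phi S_i$ (mM). Biomass gain equals substrate consumption
one-to-one; there is no explicit yield coefficient, so the OD-per-mM
conversion is absorbed into the rate constants.

**MMM.** Uptake of each pool is saturating and independent:

$$\frac{d\phi P}{dt} = \sum_{i=1}^4
  \frac{\beta_i\,\phi S_i^2}{k_i + \phi S_i}\,\phi P - d\,\phi P,
\qquad
\frac{d\phi S_i}{dt} = -\frac{\beta_i\,\phi S_i^2}{k_i + \phi S_i}\,\phi P.$$

Note the squared substrate concentration in the numerator: the per-pool
flux is the Monod-type rate $\beta_i \phi S_i/(k_i+\phi S_i)$ acting
mass-action-style on the $S_i + P$ encounter, i.e. multiplied by
$\phi S_i \phi P$. The model has $2\times4+1 = 9$ free parameters
(`count_free_parameters("mmm")`).

**Cybernetic.** Each pool gets a key assimilatory enzyme $\phi E_i$
(dimensionless level). Per-pool growth and enzyme-synthesis rates are

$$r_i = V_{max,i}\,\phi E_i\,\frac{\phi S_i}{K_{S,i}+\phi S_i},
\qquad
r_{E,i} = V_{E,i}\,\frac{\phi S_i}{K_{E,i}+\phi S_i},$$

and two control laws encode the optimality hypothesis
(`cybernetic_controls()`):

$$u_i = \frac{r_i}{\sum_j r_j}, \qquad
  v_i = \frac{r_i}{\max_j r_j}.$$

$u_i$ allocates enzyme-synthesis capacity in proportion to each substrate's
current return (so $\sum u_i = 1$); $v_i$ throttles existing enzyme
activity relative to the best available substrate ($\max v_i = 1$). The
state equations are

$$\frac{d\phi S_i}{dt} = -r_i v_i \phi P,\qquad
\frac{d\phi P}{dt} = \sum_j v_j r_j \phi P - d\,\phi P,\qquad
\frac{d\phi E_i}{dt} = u_i r_{E,i} - D_i - \alpha\,\phi E_i + \beta,$$

with constitutive enzyme synthesis $\beta$, first-order decay $\alpha$, and
a growth-dilution term $D_i$. With a shared constitutive rate the model has
$4\times4 + 3 = 19$ free parameters.

Two forms of the dilution term are provided. The default,
`dilution_mode = "standard"`, uses $D_i = (\sum_j v_j r_j)\,\phi E_i$ — the
canonical dilution of an intensive enzyme level by growth, under which
$\phi E_i$ stays non-negative whenever $\beta > 0$. The alternative
`"as_printed"` uses $D_i = (\sum_j v_j r_j)\,\phi P$, a form that appears
in parts of the cybernetic literature; it is dimensionally inconsistent for
an intensive enzyme variable and can drive enzyme levels negative, so it is
kept only for comparison. Which form any particular historical
implementation used is generally not recoverable from publications; both
are one keystroke apart here.

**Degenerate controls.** When every $r_i = 0$ (all substrate exhausted, or
all enzyme levels zero) both control laws are 0/0. The package defines
$u = v = 0$ there: no capacity is allocated to absent fluxes, and enzyme
synthesis proceeds only through the constitutive term. Initial enzyme
levels are not observable and are fixed at 0.01 for every pool
(configurable, never fitted — so they do not enter the parameter count).

## Numerical integration

`simulate_growth()` integrates either model with an adaptive explicit
Runge–Kutta 4(5) scheme (deSolve's `ode45`, rtol $10^{-8}$, atol
$10^{-10}$), using right-hand sides compiled in C. The contract is defined
behaviourally, not by integrator brand: trajectories must agree with a
fixed-step Euler oracle at step $10^{-4}$ h within $10^{-3}$ relative on
every species, and with $d = 0$ the invariant $\phi P + \sum_i \phi S_i$
must drift by less than $10^{-6}$ relative. Both properties are enforced in
the test suite, with the Euler oracle built on the pure-R derivative
functions — a route independent of the compiled integrator it checks.

Near substrate exhaustion the integrator can step a state slightly below
zero. The right-hand sides clamp states at zero before computing rates, so
a small undershoot generates no spurious flux; returned values in
$[-10^{-9}, 0)$ are clipped to zero, and anything below $-10^{-9}$ aborts
with the last valid time — that magnitude indicates a failing integration,
not roundoff.

## Interpolation, growth rates and lags

Sparse batch measurements are densified with a natural cubic spline
(`interpolate_series()`), by default onto a 49-point uniform grid — the
training-set size also used as $N$ in the AIC. Negative interpolants are
clipped to zero. Replicates are interpolated independently and then
averaged on the common grid.

Growth rates are slopes of ordinary least squares on $\ln(\mathrm{OD})$
within explicit, user-chosen windows (`estimate_growth_rate()`). Windows
are deliberately inputs rather than inferred: on a multi-auxic curve the
phase boundaries are a judgement call and the rate depends on them.

`detect_lags()` formalizes the "switch points" one marks by eye: maximal
intervals where the centred finite-difference rate of (running-mean
smoothed, window 3) $\ln(\mathrm{OD})$ falls below a threshold, by default
10% of the maximum instantaneous rate. An interval that extends to the end
of the series is treated as the terminal plateau and dropped unless
requested. Lag detection is intended to run on the spline-interpolated
curve; on a raw half-hour grid a sub-hour lag is smeared below
detectability by the smoothing window itself.

## Parameter estimation

`fit_model()` minimizes a weighted sum of squared deviations between
simulated and observed species, $\sum_s w_s \sum_t (sim_s(t)-obs_s(t))^2$,
with default weights $w_s = 1/\max_t obs_s(t)^2$ so that biomass (OD of
order 1) and pools (mM of order 1) contribute comparably. The observed
initial state seeds the simulation; a failed integration returns $+\infty$
and the move is simply rejected.

The optimizer (`anneal_simplex()`) is a hybrid of the Nelder–Mead simplex
and simulated annealing: every stored vertex objective is perceived through
a positive log-distributed thermal fluctuation proportional to the
temperature, and every trial point through a negative one, so uphill moves
are accepted with Metropolis-like probability and the algorithm reduces to
the plain simplex at zero temperature. The schedule, which the literature
on this family of methods leaves open, is: initial temperature `"auto"`
(the standard deviation of the objective over 20 seeded random parameter
draws), geometric cooling by 0.9 with 50 simplex steps per level, annealing
down to $10^{-3}$ of the initial temperature, then a zero-temperature
polish from a freshly built simplex around the best point seen (the
annealed simplex is typically collapsed and makes a poor polish start).
Three restarts are run — the first from the centre of the search box, the
rest from random draws — and the best result wins. All positive parameters
are searched in log space within $[10^{-3}, 10^{2}]$ by default, which
makes the bounds and step sizes scale-free. Restart $r$ re-seeds the
generator with `seed + r`, so fits are reproducible bit-for-bit.

## Model comparison

`compare_models()` simulates both fitted models on the common grid and
reports, per species, the Pearson correlation $r$, $R^2 = r^2$, and
$\mathrm{AIC} = N\log(\mathrm{SSE}/N) + 2p$ with the natural logarithm,
$N$ the interpolated grid size (49 by default) and $p$ the free-parameter
count (9 vs 19). Both $r$ and $r^2$ are emitted explicitly. AIC is computed
per species — five values per model — and winners are counted separately by
higher $r$ and by lower AIC; differences below $10^{-9}$ are ties credited
to neither model. On data generated by either model with small noise, the
generating model wins the majority of species (a property enforced in the
tests for both directions).

## Clustering depletion profiles

Per-amino-acid profiles are normalized to fraction remaining
(`normalize_profiles()`), clustered by average-linkage hierarchical
clustering on Euclidean distance, and the number of clusters is chosen by
maximum mean silhouette width over a candidate range
(`cluster_profiles()`, default 2–8). The method is deterministic and
robust at $n = 19$; crucially, $k$ is selected rather than imposed, so
recovering the expected four groups from synthetic data is a genuine test,
not a restatement of the input. `depletion_times()` finds the first
linear-interpolated crossing below a negligibility threshold (default
0.01 mM), and `order_clusters()` relabels clusters by ascending mean
depletion time (ties broken by size, descending).

## Regulon coherence

`coherence_score()` measures co-expression of a gene set across a time
course as the mean over unordered gene pairs of $\operatorname{atanh}(r)$,
the Fisher Z-transformed Pearson correlation of $\log_2(\mathrm{TPM}+1)$
profiles (replicates averaged first). Averaging on the z scale rather than
transforming the average is what lets tightly co-regulated sets score well
above 1, which raw mean correlations cannot. Correlations are clipped at
$|r| \le 1-10^{-6}$, so identical profiles score about 7.25 instead of
infinity; constant genes are excluded with a warning. The statistic is
calibrated (expected score $\approx 0$ for independent genes) and monotone
in the true within-set correlation — both properties are verified by
simulation with `generate_expression()`, which draws gene profiles from a
shared latent temporal signal mixed with independent noise at the weight
implied by the target pairwise correlation $\rho$.

## The synthetic experiment

`generate_experiment()` produces every input the pipeline needs, with
ground-truth metadata sufficient for all recovery tests: the generating
parameters, the lumping scheme, the noiseless lumped trajectory and
per-amino-acid matrix, pool depletion times and switch events.

The defaults emulate the defined-medium study conditions: 19 amino acids at
0.2 mM each, grouped 3/4/9/3 (pool totals 0.6, 0.8, 1.8, 0.6 mM), starting
OD600 0.1, sampled every 0.5 h for 10 h, two replicates. Measurement noise
is Gaussian truncated at zero with SD equal to 5% of each species' initial
concentration — 0.01 mM per amino acid and 0.005 OD units, typical of NMR
quantification and OD600 reads.

The default cybernetic generating parameters are **invented values**, not
estimates from any real dataset. They were chosen once, before the recovery
tests were frozen, so that (i) the rate ordering
$V_{max,1} > \dots > V_{max,4}$ yields sequential depletion of pools 1–3 at
roughly 2.4, 4.9 and 9.0 h, (ii) the curve is genuinely triauxic — two
internal growth lags at the first two switches — and (iii) pool 4 supports
growth so slowly that it is barely touched within the 10 h horizon,
mirroring a "negligibly used" last group. A ground-truth *switch event* is
a pool depletion after which at least one other pool is still present and
is subsequently consumed by more than the negligibility threshold; under
the defaults there are exactly two, matching the two detectable lags. The
default MMM generating parameters are likewise invented, and were chosen
for identifiability: every pool's Michaelis constant is small relative to
its concentration range and every pool is essentially exhausted within the
horizon, so the maximum-rate constants and the death rate are individually
well constrained by 5%-noise data (an experimental-design consideration,
settled with a profile-likelihood-style check before the defaults were
frozen).

Within a pool, member amino acids are split proportionally with a smooth
per-amino-acid log-normal jitter profile (random intercept and slope in log
time, SD 0.1) and renormalized so pool sums are preserved exactly
(`disaggregate()`). A constant multiplier would cancel under the per-time
renormalization and make within-pool members identical after profile
normalization; the time-varying form is the simplest construction that
separates members' depletion times while keeping groups distinct. No claim
is made that real within-group heterogeneity looks like this.

What the generator does *not* emulate: systematic (non-Gaussian) measurement
error, OD saturation and calibration drift, cross-feeding between amino
acid pools, peptide-bound substrates, or any transcriptome-level readout
beyond the latent-signal expression matrices. Passing recovery tests on
these synthetic data therefore demonstrates the pipeline's correctness and
power under its own assumptions, not the adequacy of either growth model
for any particular organism.

## Problem sizes and runtime choices

The shipped tests and the pipeline default to the study-condition sizes: a
21-point sampling grid interpolated to $N = 49$, 19 amino acids, two
replicates; fits use the default annealing schedule (roughly $2\times10^3$
to $4\times10^3$ objective evaluations per restart, three restarts), which
completes in well under a minute per model on one core thanks to the
compiled right-hand sides. Oracle-equivalence checks use a handful of
random parameter sets per model; coherence calibration uses 500 simulated
sets at $\rho = 0$ and 60 per $\rho$ for monotonicity.

## Known limitations

- The two models share the no-explicit-yield convention; fitted rate
  constants therefore conflate yield and kinetics, and are comparable only
  within this convention.
- Per-species AIC uses the interpolated grid size as $N$; interpolated
  points are not independent observations, so AIC differences are a ranking
  device (as in the comparison table), not a calibrated evidence scale.
- The annealed simplex is a heuristic global optimizer: with the default
  budget it reliably finds the global basin on the shipped study
  conditions, but pathological parameter landscapes can defeat any such
  schedule; raise `restarts` or slow the cooling for harder problems.
- `"as_printed"` enzyme dilution can push enzyme levels negative; it exists
  for comparison, and trajectories that cross $-10^{-9}$ abort rather than
  being silently clipped.
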