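---
title: "Methods: DoE optimization of iPSC suspension-culture media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DoE optimization of iPSC suspension-culture media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggdoe)
```

# Scope and model

`aggdoe` analyzes bioreactor media-screening campaigns in which five
high-molecular-weight additives (DS, HS, PVA, PA, PEG) are varied jointly
and each reactor is followed for four days with daily triplicate cell
counts and ≥ 30 aggregate diameter measurements, plus endpoint assays
(flow-cytometry pluripotency markers, ΔCt-normalized qPCR, viability).

All regression is multiple linear regression on the *coded* factor scale
(`−1 … +1`, affine in concentration by default, optionally log-spaced) with
the full two-factor interaction model

$$y = \beta_0 + \sum_j \beta_j x_j + \sum_{j<k} \beta_{jk} x_j x_k + \varepsilon,$$

optionally extended by higher-order product terms. Coding makes coefficient
magnitudes directly comparable across factors with different units, which
is the convention behind DoE coefficient plots. With five factors the model
has p = 16 parameters; the default campaign spends 16 D-optimal runs plus
3 replicated center points (19 media conditions over 2 batches), leaving
three residual degrees of freedom — enough to estimate every interaction,
at the price of wide intervals. That trade-off is inherent to the campaign
size, not to the implementation.

# Design generation

The candidate set is the 3-level full factorial grid of coded points
(3⁵ = 243 for five factors); three levels keep the mid level in the
candidate space, consistent with the use of center points. The D-optimal
search maximizes `det(X'X)` by coordinate exchange: starting from a random
candidate subset, each run's coordinates are cycled through the candidate
levels of that factor, keeping any exchange that increases the determinant,
until a full pass brings no improvement; 20 seeded restarts guard against
local optima and ties break to the first design found, so results are
reproducible. On small instances (enumerable candidate spaces) the exchange
search attains the exhaustive optimum, which the test suite verifies by
enumeration with repetition allowed — replicated runs are legitimate
designs, so the oracle must consider them.

Designs are scored by log-determinant and by G-efficiency,
`100·p / d_max` with `d_max = max_x n·x'(X'X)^{-1}x` over the candidate
set: 100% for orthogonal saturated designs, less as worst-case prediction
variance grows. Center points are appended at the factor midpoints; batch
assignment deals center points round-robin first (each batch must contain
at least one, otherwise normalization is impossible — fewer centers than
batches is an error) and then deals the remaining runs round-robin in a
seeded shuffled order. The batch split is treated purely as a post-hoc
label for normalization; no blocking factor enters the model.

# Growth kinetics and the aggregate stability statistic

The specific growth rate K (1/day) is the least-squares slope of log mean
daily count against day, replicates averaged per day before the log;
doubling time is `ln 2 / K` (undefined for non-growing cultures). Day 0
(seeding) is included when counted.

Aggregate stability rests on converting diameters to volumes and volumes to
cell numbers with two constants: the single-cell diameter (10 µm, so
`V_c = (4/3)π·5³ = 523.6 µm³`) and the random close-packing fraction 0.64.
From the baseline-day mean diameter: `V₁ → N₁ = (V₁/V_c)·0.64`, projected
forward `N = N₁·e^{K·h}` over the horizon `h` (default 3 days), and back to
a predicted volume `V_P = N·V_c/0.64`. The percent error
`(V_obs − V_P)/V_obs` is computed **on volumes**, as the defining equation
states, with diameters as derived views; it is a continuous ratio, so
fractional cells-per-aggregate are never rounded.

One indexing decision was genuinely open: the projection exponent is
`e^{K·3}`, yet culture-day labels would make "day 1 to day 3" a 2-day
interval. We resolve it by comparing the prediction against the measurement
taken `h` days *after* the baseline day (day 4 of a 0–4 series for the
defaults), so that the chain is exactly self-consistent: noise-free
exponential growth without fusion yields a percent error of 0 to machine
precision, which is also what makes the statistic interpretable (positive ⇒
fusion, negative ⇒ fragmentation). `compare_day` can be set explicitly to
reproduce the literal day-3 comparison, in which case the 3-day exponent
over a 2-day interval biases the error negative by `1 − e^{−K}`.

qPCR levels are normalized as `1000/2^{ΔCt}` with
`ΔCt = Ct_target − Ct_housekeeping`, so higher expression gives larger
values; the ΔCt orientation is chosen to make that monotonicity hold.

# Model quality metrics

* **R²** is the corrected coefficient of determination (about the response
  mean); a constant response is defined to have R² = 0.
* **Q²** is `1 − PRESS/SS_tot` with PRESS computed by the hat-matrix
  identity `e_i/(1−h_ii)`; the test suite proves the identity against
  explicit leave-one-out refits. Q² may be (very) negative in saturated
  19-run/16-parameter fits, where several leverages approach 1 — it is
  reported as computed, never clipped, and `-Inf` when a leverage is
  numerically 1.
* **Model validity** partitions residual SS into pure error (within the
  replicate groups — the center points) and lack of fit, and maps the
  F-test p-value through `1 + 0.57647·log₁₀(p)`, capped at 1. The constant
  is the standard DoE-software convention and makes p = 0.05 correspond
  exactly to the customary 0.25 floor, with 0.05 the significance level
  used throughout.
* **Reproducibility** is `1 − (pooled replicate variance)/(total
  variance)`; > 0.5 is the conventional acceptability reading.

**Center-point normalization** rescales each response within a batch by
`grand center mean / batch center mean`, removing multiplicative batch
drift exactly while preserving the grand center mean; it is idempotent and
errors on batches without (or with zero-mean) center responses. A known
cost, visible in simulation: with only three center replicates the scale
estimate is noisy and batch-correlated, which OLS confidence intervals do
not model. At the default noise level this depresses nominal 95% coverage
of true coefficients to roughly 85% after normalization, while fits on raw
responses cover at ~95%. The packaged `recovery_rate()` therefore fits raw
responses — it is a check of the estimation machinery, not of the
normalization step — and analysts should treat post-normalization intervals
as slightly anti-conservative.

The negative-log transform `−log₁₀(y/100 + ε)`, ε = 10⁻⁶, is available for
left-skewed percent responses that pile up near 100% (applied by default to
OCT4 and TRA-1-60 flow frequencies); ε guards exact zeros, and criteria/Cpk
limits are mapped through the (decreasing) transform when optimizing such
responses.

# Desirability optimization

Criteria use the Derringer–Suich piecewise-linear form with unit exponents
(the simplest defensible default; the shape is configurable territory we
deliberately did not multiply). Overall desirability is the weighted
geometric mean — zero as soon as any criterion is fully violated. The
setpoint search runs 20 seeded Nelder–Mead starts (Brent for one factor)
with candidates clamped to the coded box; the reported optimum is never
worse than any start point, and tests pin it against dense grid oracles.

At the setpoint, each criterion gets: the prediction-interval SD
(`σ·sqrt(1 + x'(X'X)^{-1}x)`, residual plus leverage — the "natural
tolerance" of a future run), Cpk = distance from predicted mean to the
nearest specification limit in 3-SD units, and the closed-form normal
probability of failure (Monte Carlo available as a cross-check; the two
agree within binomial error). **Factor contributions** are a documented
reconstruction — the span of the predicted response as one factor sweeps
its range with the others fixed at the setpoint, normalized to 100% within
a response — since the originating software's formula is proprietary; with
interactions, a factor's contribution legitimately depends on where its
partners sit (zero partner ⇒ zero contribution of a pure-interaction term).
Spans below numerical noise are treated as flat. Setpoint profiles sweep
one factor and carry the prediction band, which widens toward the design
edges via leverage.

# The synthetic campaign generator

The generator is first-class, tested code: it encodes the statistical
structure the analysis assumes and provides the ground truth for every
property and acceptance test.

* **Growth**: `K(x) = K₀ + x'β_K`, K₀ = 0.5/day (doubling ≈ 1.4 days,
  typical for healthy iPSC aggregates), effects of a few percent per
  factor; seeding density N₀ = 1.1×10⁵ cells/ml; triplicate counts with
  10% lognormal CV, mean-unbiased.
* **Aggregates**: 150 aggregates per reactor initialized on day 1 with
  lognormal diameters (median 65 µm, σ_log = 0.15 — a 65 µm aggregate holds
  ~180 cells at 0.64 packing); each day the volume grows by `e^K`
  (cell-level growth), then a Poisson number of pairwise fusions
  (rate λ_f per aggregate per day; volumes add, count drops by one,
  total volume conserved) and binary splits (rate λ_b; equal halves).
  λ_f is log-linear in the coded settings, baseline 0.1/aggregate/day at
  the center and suppressed by HS, PEG, DS with an HS:PEG synergy — the
  fusion-limiting biology the campaign exists to find. 30 diameters are
  sampled per day.
* **Endpoint assays**: flow-marker frequencies are generated on the logit
  scale (intercepts ≈ 88–94%) and back-transformed, so bounds are respected
  and the neglog path is exercised; qPCR levels and viability are linear in
  the model terms with Gaussian noise. Multiplicative lognormal batch
  offsets (σ_log = 0.05) are applied to the qPCR responses — the assay
  realistically re-run per batch — and are exactly the drift center-point
  normalization removes; bounded percent responses are left undrifted so
  they stay within 0–100.

What the generator does **not** emulate: nutrient depletion or growth-rate
saturation, shear-dependent breakage mechanics, per-aggregate tracking,
non-spherical or density-varying aggregates, flow-gating artifacts, or
heavy-tailed measurement error. Passing tests therefore demonstrate that
the pipeline recovers truth under its own assumptions — linearity in coded
space, lognormal sizes, Poisson fusion — not that real cultures satisfy
them. The true distributional form of measured diameters is unknown
(only means/SDs are typically reported); lognormal is an assumption.

# Numerical choices and test scale

Determinism throughout: every stochastic routine takes an explicit seed and
restores the caller's RNG state. Exchange-search ties break first-found;
improvement thresholds are 10⁻¹². Degenerate inputs fail loudly (rank
deficiency, n_runs < p, zero observed volume, batches without centers,
nonpositive counts named by run and day) rather than silently degrading.

Test problem sizes were chosen so the full suite runs in minutes on one
core while keeping estimates stable: exhaustive design oracles on 3×3
candidate grids; 100 random instances for the PRESS identity; 50 simulated
campaigns for the fit-quality medians (median worst-case R² ≈ 0.92,
median validity ≈ 0.5 at default noise); 500 campaigns for the 95%-CI
coverage study; 1000 replicates for growth-rate bias; fusion monotonicity
on 4000-aggregate populations over a five-point rate grid.

# Known limitations

* With 19 runs and 16 parameters the design is near-saturated: Q² is
  pessimistic, validity has a single lack-of-fit degree of freedom, and
  coefficient CIs rest on three residual df. The machinery supports larger
  `n_runs` directly.
* Center-point normalization with three replicates adds batch-correlated
  scale noise (see above); more centers per batch would shrink it.
* The default factor concentration ranges are placeholders anchored to
  literature-typical values; real campaigns must supply their own.
* Factor contributions and probability-of-failure are principled
  reconstructions of proprietary conventions, documented here, and should
  not be expected to match other software's numbers exactly.
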