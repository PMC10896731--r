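---
title: "Attainable yields and yield-gap trends: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attainable yields and yield-gap trends: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldgaps)
```

## The estimand

This package estimates, year by year, the *attainable yield* of a crop — the
95th percentile of observed yields among census units sharing biophysical
conditions — and everything that follows from comparing that ceiling with
the actual yield floor: yield gaps, their trends, projected closure times, a
trajectory typology and stagnation risk. The unit of observation is one
(administrative unit, crop, year) census record carrying yield `y` (t per
harvested ha), harvested area `a` (ha) and a covariate vector.

Working with a high quantile rather than a mean has two consequences that
shape the whole design. First, every statistic must be *area-weighted*:
census units differ in harvested area by orders of magnitude, and a surface
calibrated on record counts would mean little in production terms. Second,
the quantile level itself must be enforced: the check loss constrains the
share of area above the surface only weakly, so the fit is regularized
against its achieved calibration.

## The loss and its calibration penalty

For predictions `q_i` the area-weighted check loss is

$$\mathrm{LF}_\tau = \frac{\sum_i w_i\,|y_i - q_i|\,a_i}{\sum_i a_i},
\qquad w_i = \begin{cases}\tau & y_i > q_i\\ 1-\tau & y_i \le q_i\end{cases}$$

with $\tau = 0.95$. Ties ($y_i = q_i$) count as on-or-below, consistently in
the loss, in the calibration target and in every reported share. The
regularized objective adds

$$\lambda = \mathrm{s.d.}(y)\; \Big(\sum_i a_i\Big)\,
  \Big|\frac{\sum_{j:\,q_j > y_j} a_j}{\sum_i a_i} - \tau\Big|,$$

zero exactly when the area share under the surface equals $\tau$. `s.d.(y)`
is the unweighted sample standard deviation of the fit-year response.
$\lambda$ is implemented exactly as written, which means it scales with the
total harvested area; an alternative normalized by $\sum a$ would only
rescale the trade-off and is not offered (the calibration step below makes
the trade-off moot in practice).

**Optimization.** The check loss is minimized exactly: the problem is a
linear program, solved by a Mehrotra predictor–corrector primal–dual
interior-point iteration on the standard quantile-regression dual
(`rq_fit_ip()`), with the area weights folded into the rows (the check loss
is positively homogeneous). Convergence is declared at a relative duality
gap below 1e-10; rank-deficient designs are refused.

$\lambda$, however, is piecewise constant in the coefficients — its gradient
is zero almost everywhere — so joint smooth optimization of the regularized
objective is ill-posed. The implementation instead calibrates after the LP
solve: the area share on/below the surface is a non-decreasing step function
of the intercept, so the share-optimal intercept shift is the area-weighted
$\tau$-quantile of the residuals, computed in closed form (equivalent to a
converged bisection). Both neighbouring steps of the share function are
evaluated and the closer to $\tau$ is kept, unless the original LP solution
has a lower combined objective, in which case it is retained. With discrete
area weights the achievable share is quantized; on panels of 1,000+ records
the achieved share is within ±0.01 of $\tau$, closer as records get smaller
relative to the total.

## Covariates and normalization

Covariates follow the field-standard set: GDD (base 0 °C, computed from
monthly mean temperatures as $\sum_m \max(\bar T_m, 0)\,d_m$ — monthly
climatology, no daily interpolation), MAP, Oliver's annual precipitation
concentration index $100\sum p_m^2/(\sum p_m)^2$, the irrigated fraction
scaled through time by ratios of area equipped for irrigation (linearly
interpolated, extrapolated from the last two observations, clamped to
[0, 1]), soil available water capacity, organic carbon and pH over the top
30 cm, the share of area steeper than 30°, and for wheat a binary
vernalization factor. Two VF conventions exist in the literature — coldest
month in the closed interval [−8, 5] °C versus at most 8 °C — and both are
offered; the interval convention is the default.

All fitting happens in z-score space so coefficients are unitless and
comparable across years: one factor set (mean and population standard
deviation) per crop, computed once over all quality-passed records pooled
across years, for covariates and response alike. Products and powers are
computed on z-scored covariates. Zero-variance covariates are an error: the
caller must drop them (the wheat-only VF being the usual case).

## Quality filtering

Within each (crop, year) group, records are rejected when the harvested-area
fraction exceeds 3 (a multicropping index above 300%) or when yield exceeds
the area-weighted 97.5th-percentile yield plus twice the standard deviation
of the group's yields. The percentile is area-weighted (left-continuous
weighted empirical CDF, ties broken by yield then unit id — deterministic on
any input); the 2-s.d. screen uses the unweighted sample s.d., since the
weighting is specified for the percentile only. On clean synthetic panels
the rejection rate stays below 3%.

## Model selection in time

Selecting terms on annual data risks chasing year-specific noise into the
coefficient trajectories. Selection therefore happens on a smoothed
dataset: eight non-overlapping half-decadal layers (central years 1975,
1980, …, 2010, each averaging its ±2-year window with area weights, one
pseudo-record per unit per layer), with linear and quadratic time terms
appended to the candidate set.

Two phases operate on the pooled layers:

1. **Significance pruning.** Coefficient intervals come from a 200-replicate
   case-resampling bootstrap; terms whose interval overlaps zero are removed
   one at a time, starting with the interval most centrally overlapping zero
   (smallest $|lo+hi|/(hi-lo)$). Resampling is *by unit* (cluster
   bootstrap): each unit contributes one pseudo-record per layer, and
   resampling rows would treat those eight records as independent,
   understating coefficient variance roughly $\sqrt{8}$-fold and letting
   unit-persistent noise covariates appear significant.
2. **Cross-validated deletion.** Each generation forms child models by
   deleting one deletable term; each child is scored by leave-one-layer-out
   cross-validation (fit on seven layers, check loss on the held-out layer,
   summed over the eight folds; the same pooled normalization factors on
   every fold keep losses comparable). The best child is adopted while it
   improves on its parent; on the first non-improving generation one further
   generation is explored before finalizing, guarding against a local
   minimum. Equal child losses delete the term appearing later in spec
   order.

The intercept, the irrigation term, the irrigation–precipitation cross term
and the time terms are never deleted in either phase. After selection the
time terms are stripped and coefficients are fit year by year on annual
data.

## Bootstrap inference

All confidence statements derive from case-resampling bootstraps of the fit
year's records (each record keeping its area weight), refit with the full
regularized procedure — 1,000 replicates by default, fewer where a consumer
scales the analysis down. Intervals are empirical percentiles with linear
interpolation between order statistics (R's default convention; the
95% level uses the 2.5th and 97.5th percentiles, and a 75% level supports
the sensitivity analysis). A trend is significantly positive (negative) when
both percentile bounds of the per-realization slopes share that sign. Seeds
are laddered — master seed → year → replicate → attempt — so any single
replicate is reproducible in isolation; failed refits are redrawn up to
three times and more than 5% irrecoverable failures abort the ensemble.

## Trends, closure times and typologies

Year-specific quantities are ±2-year windowed area-weighted averages, each
year weighted by its reported harvested area; missing years drop out of the
window. Gap trends are per-realization OLS fits of annual gaps over
1998–2012 with the intercept referenced to 1998, so the closure time
relative to 2010 is $t_{\mathrm{close}} = -x_0/x_1 - 12$; a unit is reported
as a closure time (median over realizations), as `no_trend` when the slope
bounds differ in sign, or as `widen` when the gap significantly grows (the
trend lines crossed in the past). With a single realization — e.g. when
validating against ground truth — the slope's OLS t-interval substitutes for
the percentile bounds.

Area-share tables ("share of harvested area with significant growth in X
over period P") use the per-realization endpoint difference of windowed
values, sign-tested via percentile bounds, weighted by reference-year areas
(2000 for the full period and the last decade, the period start for the
first decade); a regression-slope mode is available as an alternative.
Globally averaged changes divide the fitted global slope by the windowed
base-year value; realizations with non-positive base gaps are rejected
(near-zero gaps make relative rates unbounded) and surviving rates outside
mean ± 4 s.d. are screened two-sidedly (the literal one-sided reading is
available as a flag). A fixed-area counterfactual recomputes the global
series with every unit's weight frozen at a baseline year, isolating the
effect of cultivated-area shifts from yield change.

The typology cascade — `ceiling_pressure` if the gap is significantly
closing *or* the ceiling is not significantly growing; otherwise
`stalled_floor` if the floor is not significantly growing; otherwise
`steady_growth` — is exhaustive and mutually exclusive by construction over
units with determinate calls, so area shares always total 100%. Stagnation
is a plateau after growth: a value-continuous broken-stick regression over
1986–2012 with the slope break fixed at 2000, flagged when the pre-break
slope interval is entirely positive and the lower post-break limit is
negative (an upper post-break limit above zero does not veto the flag; the
rule is deliberately asymmetric). Intervals here are ordinary
least-squares t-intervals — the minimal reading, since no ensemble exists at
this stage. The risk ratio conditions on gaps significantly closing during
1986–2000 with projected closure within 30 years, and reports alongside the
headline ratio the reversion-to-the-mean controls restricted to the third
and the top quartile of prior yield growth (both strata are reported because
the two defensible readings differ).

## The synthetic-data generator

`generate_panel()` emulates the statistical geometry the model assumes,
with known ground truth: per-unit covariates drawn from documented ranges
(GDD 1,000–9,000 degree-days, MAP 200–3,200 mm, PCI 9–70, Beta-distributed
irrigated fractions, plausible soil values), a true ceiling
$x'\beta(t)$ on z-scored covariates floored at 0.1 t/ha, log-normal
harvested areas (meanlog 7, sdlog 1.5 — heavy-tailed like real census
units), and actual yields equal to ceiling × attainment. Defaults are the
study conditions all validation runs under:

- **Ceiling growth 1% per year** of the year-2000 level, linear in time.
- **Attainment** Beta(4, 1.6) per unit (mean ≈ 0.71, i.e. a ~30% relative
  gap), with multiplicative year-to-year noise capped at the ceiling.
- **Exceedance 5%**: a Bernoulli(0.05) *unit-level* "frontier" mechanism
  replaces a unit's attainment path with Uniform(1, 1.1) multiples of the
  ceiling. This pins the area-weighted 95th percentile of yield at the
  ceiling exactly — the estimand equals the generating surface — while
  keeping unit time series free of spikes. (A record-level mechanism would
  inject ~50% jumps into individual series and confound trend detection
  with outlier noise; real frontier exceedance is a property of
  consistently high-attainment regions.)
- **Noise** log-s.d. 0.03 per year. This represents the *effective*
  year-to-year noise after the ±2-year averaging the method applies to all
  year-specific data; raw census yields vary more. The choice is a design
  condition fixed by a power argument: a 15-year window gives an OLS slope
  noncentrality of roughly $0.01 \times 16.7 / \sigma$ for a 1%-per-year
  trend, so the trends the typology is built on are identifiable only for
  $\sigma \lesssim 0.037$.
- **Scenarios** control per-unit trajectories: `steady_growth` (constant
  attainment under a growing ceiling), `stalled_floor` (floor frozen at its
  first-year level), `ceiling_pressure_gapclose` (attainment ramps toward
  0.92), `ceiling_pressure_flatceiling` (ceiling held flat). Ground truth
  records per-unit true ceilings, attainments and slopes.

What the generator does *not* emulate: spatial autocorrelation, covariate
drift (the climatology is static, as in the source analysis), reporting
gaps and administrative reconciliation artifacts, area dynamics (areas are
static per unit), and flat-ceiling units are invisible to the globally
shared fitted surface (their ceilings deviate from $x'\beta(t)$ by a
unit-level factor). Passing tests therefore demonstrate that the machinery
recovers known structure under the model's own assumptions — not that real
census data satisfy those assumptions.

## Numerical choices

- LP duality-gap tolerance 1e-10 relative, at most 100 iterations; normal
  equations solved by Cholesky with a 1e-12 relative ridge.
- Intercept calibration via the closed-form weighted residual quantile
  (equivalent to converged bisection); both adjacent steps of the share
  function compared.
- Weighted quantiles use the left-continuous weighted ECDF,
  $\inf\{t: F(t) \ge p\}$, ties broken by value then id.
- Predictions are floored at 0 t/ha with a warning (yields are
  non-negative); covariates outside the training range warn but predict.
- Years with fewer than five records per coefficient are skipped with a
  warning rather than fit.
- Input years outside 1973–2012 are accepted; windows simply use what
  exists.

## Validation problem sizes

The shipped validation suite exercises: calibration on a 2,000-unit panel
(achieved share within ±1 point of 95%); equivalence of the LP solve with
exhaustive grid search on 50 tiny instances; exact (1e-6) recovery of
noiseless surfaces; coverage of bootstrap percentile intervals across 200
independent 500-unit panels at B = 100 (nominal 95%, accepted 90–98%);
decoy-covariate rejection across 25 selection runs on 150-unit panels;
typology recovery over ≥ 80% of harvested area on a 400-unit mixed-scenario
panel; and stagnation detection rates with their causal and null risk-ratio
worlds. These sizes are the package's validation design; scaling any of
them up only narrows the Monte-Carlo envelopes.

## Known limitations

- The attainable surface is global in covariate space; units whose true
  ceilings move idiosyncratically (the flat-ceiling scenario) are
  represented only through their covariates.
- Single-realization significance falls back to OLS t-intervals, which
  ignore serial correlation within a unit's series.
- The calibration step adjusts the intercept only; a full re-fit under the
  calibrated constraint is available conceptually (one more LP) but not
  implemented, as the achieved shares already sit within the quantization
  limit of the area weights.
- Quantile crossing between years is not prevented: each year is fit
  independently, which is the point of the design (trends emerge from the
  data, not from smoothing), but adjacent-year surfaces can disagree for
  sparse crops.
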