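---
title: "Methods: climate-driven ozone change and mortality impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-driven ozone change and mortality impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ozimpact)
```

This vignette documents the models behind `ozimpact`, the assumptions they
make, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical decisions a
maintainer would want written down.

## The estimand

The package estimates the excess non-accidental deaths attributable to a
climate-driven change in summer (May–September) ground-level ozone across a
set of urban communities:

$$M = \{\exp(\beta\,\Delta x) - 1\}\times N,$$

where $\beta$ is the pooled log relative risk of daily mortality per ppb of
maximum daily 8-hour average ozone (MDA8), $\Delta x$ the change in mean
summer MDA8 between a reference period and a future period, and $N$ the
baseline death count. Everything else in the package exists to produce
$\beta$, $\Delta x$ and their uncertainties.

## Exposure metrics

`compute_mda8()` scans the 17 eight-hour windows fully contained in a
calendar day (start hours 0–16). Cross-midnight windows are excluded: the
daily metric is defined within the day, and time-zone bookkeeping is out of
scope. A window is valid when at least 6 of its 8 hours are present
(75% of 8, rounded up), and a valid window averages its available hours
only. No additional whole-day completeness rule is applied before taking
the daily maximum — the per-window rule is the only completeness filter.
`design_value()` implements the regulatory 3-year mean of yearly
fourth-highest MDA8 with the 75 ppb attainment threshold.

Coordinates are projected equirectangularly about the latitude centroid of
the point set ($y = 111.32\,\mathrm{lat}$,
$x = 111.32\,\mathrm{lon}\cos(\mathrm{lat}_0)$). At the sub-1000-km scale
of one US region the distortion relative to geodesics is a fraction of a
percent, and the projection keeps all distances exactly reproducible.
Nearest-station linkage breaks exact distance ties by the smallest station
identifier so that linkage is deterministic and row-order invariant.

## The space-time ozone model

$$Y(s,t) = X(s,t)\,\beta_r + e(s,t),$$

with $X$ = (1, temperature °C, GHI W/m², cloud cover %) and one coefficient
vector per state ($\beta_r$), all states sharing the residual process. The
response is untransformed ppb: summer MDA8 shows little skewness, and an
additive model keeps $\Delta x$ interpretable. Residuals are a mean-zero
Gaussian process with separable exponential covariance

$$\mathrm{Cov}\{e(s_1,t_1), e(s_2,t_2)\}
  = \sigma^2 \exp(-\lVert s_1-s_2\rVert/\rho_s)\,\exp(-|t_1-t_2|/\rho_t).$$

The *effective range* — the separation at which correlation falls to
0.05 — is $3\rho$ for this family.

**Priors.** $\rho_s \sim U(10, 350)$ km and $\rho_t \sim U(0, 5)$ days,
chosen through their effective ranges (30–1050 km, 0–15 days);
$\sigma^2 \sim$ inverse-gamma(0.01, 0.01) as a proper, essentially
non-informative conjugate choice; independent $N(0, 10^6)$ priors on each
regression coefficient. All are arguments of `oz_priors()`.

**Sampler.** `fit_mcmc()` runs Gibbs updates for $\beta_r$ (conjugate
normal) and $\sigma^2$ (conjugate inverse-gamma) and a joint random-walk
Metropolis step on $(\log\rho_s, \log\rho_t)$, with proposals reflected at
the transformed prior bounds and the log-scale Jacobian included in the
acceptance ratio. The two decay scales are updated jointly because their
posteriors are mildly correlated and a joint step costs one Cholesky pair
either way. The proposal step size adapts every 50 burn-in iterations
toward a 20–45% acceptance rate and is then frozen so the retained chain is
a fixed-kernel Markov chain. Defaults follow the 3000-retained /
1000-burn-in protocol (`n_iter = 4000, burn_in = 1000`), with no thinning.

**Likelihood.** Complete station-by-day panels use the Kronecker identity
$\Sigma = \sigma^2 R_s \otimes R_t$: whitening by the two small Cholesky
factors gives the exact log density at
$O(n_s^3 + n_t^3 + n_s n_t (n_s + n_t))$ cost instead of $O((n_s n_t)^3)$.
Panels with missing responses drop the missing entries and use the dense
covariance restricted to observed pairs — exact but only sensible for small
panels; no imputation is attempted. A failed Cholesky gets one retry with a
relative diagonal jitter of $10^{-8}$, then errors with advice. The
Kronecker and dense paths are cross-checked against each other in the test
suite to $10^{-8}$.

**Prediction.** `predict()` draws from the posterior predictive at new
locations for each of `n_draws` (default 100) evenly thinned parameter
draws. Conditional mode performs exact kriging given the fitted panel's
residuals (the conditional spatial covariance is a Schur complement, again
Kronecker-factored over days); because new points colocated with monitors
make that Schur complement numerically singular, an absolute nugget of
$10^{-8}$ (correlation scale) is added to its diagonal. Unconditional mode
samples the GP around $X\beta$ for pure projections.
`validate_holdout()` removes whole stations, refits, and reports RMSE and
95%-interval coverage at the held-out station-days.

**Known limitation.** There is no separate measurement-error component for
the monitors; observational noise is absorbed into the GP nugget-free
residual. This simplifies computation and matches the model the estimand
was defined under.

## Regression calibration of climate-model weather

Climate-model output is treated as an error-prone version of true weather
and the observed reference-year series as validation data: per county and
variable, `fit_calibration()` regresses observed on model output by OLS and
`apply_calibration()` uses the fitted line as the calibrated projection
(cloud cover truncated at 0). No explicit $r^2$ threshold triggers a mean
fallback: a near-zero estimated slope produces the collapse to the
reference mean by itself, which is the expected behaviour for variables the
climate model barely tracks (typically cloud cover). A hard slope-zero
fallback exists only for degenerate zero-variance or non-finite cases.
Gridded output is linked to counties by averaging cells whose centres fall
inside the county circle, or the nearest centre if none does — gridded
values are treated as point values at cell centres, deliberately ignoring
the change-of-support problem.

Calibration uncertainty is **not** propagated into the impact CI: the
fitted lines are treated as fixed. This is a stated scope decision, and the
natural next step (multiple imputation over calibration draws) is left as
future work.

## Community health models and pooling

Per community $c$, daily deaths in three age strata (<65, 65–74, ≥75)
follow an over-dispersed Poisson model

$$\log E[y_t^c] = \beta^c x_t^c + \gamma^c Z_t^c,$$

fitted by IRLS (`stats::glm.fit`) with the Pearson $\chi^2$ dispersion
scaling the coefficient covariance. Ozone enters at lag 0, 1 or 2 in
separate single-lag models, and jointly in an unconstrained distributed-lag
model whose cumulative effect is the coefficient sum with variance summed
over the full $3\times3$ covariance block. Confounders $Z$: day-of-week
indicators, age-stratum intercepts, a long-term trend spline over the
gap-compressed summer day index, age-by-trend spline interactions, and
natural cubic splines of same-day and previous-3-day mean temperature and
dew point. Spline degrees of freedom default to multi-site time-series
convention, pro-rated for summer-only series: trend 3 df per summer,
temperature 6 df (same-day and running mean each), dew point 3 df each,
age-by-trend 3 df — all configurable through `confounder_spec()`, which is
also the sensitivity hook for the usual "more trend df" check. Summers are
disjoint blocks: lags and running means never cross the September–May gap,
and rows whose lags are incomputable are dropped and counted. No population
offset is used; age-stratum intercepts absorb level differences. Exposure
is stored per ppb and reported per 10 ppb
($100\{\exp(10\hat\beta) - 1\}$ percent).

Community estimates are pooled under the two-level normal model
$\hat\beta^c \sim N(\beta^c, \hat\nu^c)$, $\beta^c \sim N(\mu, \tau^2)$.
Rather than sampling, `pool()` integrates the marginal posterior of $\tau$
deterministically: flat prior on $\mu$, uniform prior on $\tau$ over
$[0, \sqrt{20\max_c \hat\nu^c}]$ (the same $\tau^2$ span as a
$0$–$20\max\hat\nu$ grid, parameterized in $\tau$ so the uniform prior
needs no Jacobian), 2001-point trapezoid rule. Conditional on $\tau$,
$\mu$ is normal with inverse-variance weights $1/(\hat\nu_c + \tau^2)$;
mixture moments and per-community shrunken estimates are accumulated across
the grid. The prior on $\tau$ (rather than $\tau^2$) is a documented,
configurable-by-edit choice matching common two-level-normal practice. With
$\tau^2$ fixed at 0 the closed-form fixed-effect mean is returned exactly,
and the grid posterior is tested against an independent brute-force
implementation on a 10-times-denser grid.

## Projection and the impact estimate

The pipeline projects reference-period and future ozone at community
centres by **conditional** posterior prediction given the observed
reference panel, with future covariates supplied by the calibrated
climate-model weather. Both draw sets share posterior draw indices and
residual noise (common random numbers), mirroring the assumption that the
future residual covariance equals the reference period's: the paired
difference then isolates the weather-driven ozone change instead of being
dominated by residual-field noise. `delta_exposure()` averages each draw
across communities and days and takes the mean and variance of the paired
differences; the variance feeds the delta method

$$\mathrm{Var}(M) = (N\,\mathrm{years}\,e^{\beta\Delta x})^2
   (\Delta x^2 \nu_\beta + \beta^2 \nu_{\Delta x}),$$

with $\beta \perp \Delta x$ assumed. The CI is symmetric about $M$ by
construction. Decade-style totals use an explicit `years` multiplier
(default 10), with the per-year figure always reported alongside; the
baseline $N$ is held at its reference-year value with no population-growth
adjustment.

## The synthetic-data generator

`generate_network()`, `generate_weather()`, `generate_ozone()`,
`distort_to_climate_output()`, `generate_community_series()` and
`generate_mortality()` produce every input with recorded truth
(`synth_truth()`, `write_truth()`). Defaults emulate a southeastern-US
summer regime: mean ozone ≈ 53.3 ppb with residual sd 10.5 ppb
($\sigma^2 = 110.25$), spatial decay 179 km, temporal decay 1.83 days;
temperature ≈ 24.2 °C, GHI ≈ 240 W/m², cloud ≈ 4.42%; per-lag log relative
risks (0.00011, 0.00023, 0.00011) per ppb; a baseline mortality rate of
26.9 per 10,000 per summer over a 770,000-person community split into three
age strata. Climate-model distortion defaults
(`default_calib_bias()`) give truth–model $r^2$ near 0.25 / 0.03 / 0.01 for
temperature / GHI / cloud — deliberately poor, as regional climate output
tends to be. Weather is a seasonal sinusoid plus a spatially smooth AR(1)
field plus nugget noise; community mortality exposure series are AR(1)
with the ozone regime's marginal sd and lag-1 correlation.

**Injected climate signal.** A nominal signal of $s$ ppb of ozone is placed
as a mean shift in the *future climate-model temperature output* of size
$s / (\bar\beta_T \lambda)$, where $\bar\beta_T$ is the generator's true
mean temperature coefficient over the affected communities and $\lambda$
the regression-calibration slope determined by the realized reference-year
observed/model series. Because a mean shift passes through the fitted
linear calibration scaled by exactly that slope, the expected
post-calibration ozone shift equals $s$: the generator defines ground truth
on the scale the pipeline estimates. Recovery therefore genuinely tests the
fitted ozone model (its $\hat\beta_T$), the calibration application, the
projection machinery and the exposure averaging — but not the attenuation
of the calibration itself, which is a property of regression calibration
rather than a defect to detect.

**What passing tests do and do not show.** The generator matches the
analysis model's structure (that is the point of parameter-recovery
testing), so green tests demonstrate internal correctness — the estimators
recover the truth their models define — not robustness to real-data
features the generator omits: nonstationary or nonseparable residual
dependence, monitor measurement error, missing-data mechanisms that
correlate with weather, population trends, or confounders outside the
modelled set.

**Seeding.** One global integer seed fans out to per-generator streams via
`seed * 1201 + offset`; the multiplier exceeds every offset so that
different (seed, purpose) pairs never share a stream even when users seed
replicates consecutively.

## Numerical choices and degenerate inputs

* Cholesky jitter: one retry with relative $10^{-8}$ diagonal inflation;
  an absolute $10^{-8}$ nugget on conditional-prediction Schur complements
  (colocated points make them exactly singular).
* Metropolis proposals on log scales with reflection; reflection keeps the
  proposal symmetric while the $\rho'/\rho$ Jacobian accounts for the log
  transform. $\rho_t$'s lower bound 0 maps to $-\infty$, so only the upper
  bound reflects there.
* MDA8 tie and edge rules: hours outside 0–23 or duplicated are errors;
  all-invalid days return missing rather than 0.
* `fit_calibration()` with fewer than 3 matched pairs errors; zero-variance
  model output falls back to slope 0 / mean intercept with $r^2 = 0$.
* Aliased health-model columns are dropped with a warning and the model is
  refitted; an aliased *ozone* column is an error, never silently dropped.
* `pool()` demands at least two estimates and strictly positive variances;
  the $\tau$ grid's trapezoid weights make the posterior a proper discrete
  mixture regardless of grid span.

## Problem sizes used for validation

The test suite exercises the chain at sizes chosen to keep the full run in
minutes on one CPU while leaving each estimator identifiable: 15 stations ×
60 days for Gaussian-process recovery (20 seeded replicates), 3 communities
× 14 summers for health-model recovery (20 replicates), panels up to 6 × 8
for Kronecker-versus-dense likelihood equivalence, 1000 random missingness
patterns for the MDA8 oracle, and an end-to-end run at the 19-community
study scale for signal recovery and the null check. The acceptance script
(`scripts/acceptance.R`) re-runs the headline computations at those sizes
from a single seed.

## Limitations

Beyond the generator caveats above: state-specific (not spatially varying)
coefficients limit community-level projection detail; a single climate
model's output is calibrated (no multi-model ensemble); precursor-emission
changes, population change, temperature–ozone interaction and co-pollutant
adjustment are all outside the model; and the impact CI omits calibration
uncertainty by design.
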