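# ozimpact

Estimating the mortality burden of climate-driven changes in summer
ground-level ozone.

Short-term ozone exposure raises non-accidental mortality, and because
ozone formation depends strongly on weather (temperature, solar radiation,
cloud cover), a changing climate changes ozone. `ozimpact` implements a
complete statistical chain for quantifying that health burden over a
multi-community region, built for epidemiologists and environmental
statisticians who want a reproducible, testable version of the standard
multi-site design:

1. **Space-time ozone model.** Daily maximum 8-hour average ozone
   (MDA8, ppb) at monitor *s* on day *t* follows
   `Y(s,t) = X(s,t) β_r + e(s,t)`, with `X` holding an intercept,
   temperature, solar radiation (GHI) and cloud cover, `β_r` state-specific
   coefficients, and residuals from a mean-zero Gaussian process with a
   separable exponential covariance
   `σ² exp(−‖s₁−s₂‖/ρ_s) exp(−|t₁−t₂|/ρ_t)`.
   Fitting is Bayesian: conjugate Gibbs updates for `β_r` and `σ²` and
   random-walk Metropolis for `(ρ_s, ρ_t)` under uniform priors (10–350 km
   and 0–5 days — effective ranges 30–1050 km and 0–15 days). Complete
   panels use the Kronecker factorization of the covariance for fast exact
   likelihoods.
2. **Regression calibration of climate-model weather.** Per county and
   variable, observed reference-year weather is regressed on climate-model
   output; the fitted value is the calibrated projection. Uninformative
   output (the usual fate of cloud cover) collapses naturally to the
   reference-year mean.
3. **Health models.** Per community, quasi-Poisson time-series regression
   of daily deaths (three age strata) on ozone at lags 0–2 — singly and as
   an unconstrained distributed lag whose cumulative effect is the sum of
   the lag coefficients — controlling for day of week, age, seasonality and
   temperature/dew-point via natural cubic splines.
4. **Pooling.** Community log relative risks `β̂ᶜ ~ N(βᶜ, ν̂ᶜ)`,
   `βᶜ ~ N(μ, τ²)` are pooled by deterministic numerical integration of the
   two-level normal posterior over `τ`.
5. **Attributable deaths.** `M = {exp(β Δx) − 1} × N` with a delta-method
   95% CI treating the pooled risk `β` and the projected exposure change
   `Δx` as independent.

A seeded synthetic-data generator produces every input with recorded
ground truth (monitor network, weather fields, GP ozone, biased gridded
"climate model" output, mortality counts with known lag-specific risks), so
the whole chain is validated end-to-end by parameter recovery.

## Worked example

Residual correlations implied by fitted decay scales, and the
attributable-deaths arithmetic:

```r
library(ozimpact)
p <- st_covariance_params(sigma2 = 10.5^2, rho_s = 179, rho_t = 1.83)
residual_correlation(p, 0, 1)    # 0.579  -- consecutive days, same site
residual_correlation(p, 100, 0)  # 0.572  -- 100 km apart, same day

attributable_deaths(beta = 0.26/1000, beta_var = (7.65e-5)^2,
                    dx = 0.43, dx_var = 0.1556^2, N = 39514, years = 10)
#> Attributable deaths over 10 year(s): 44.2 (95% CI 3.79, 84.6)
#>   per year: 4.42;  mortality rate increase: 0.0112%
```

Here `beta` is a pooled cumulative risk of 0.26% per 10 ppb, `dx` a
projected 0.43 ppb rise in mean summer ozone, and `N` the baseline summer
death count; the 44.2 is the decade total implied by those inputs and the
CI combines both uncertainty sources by the delta method.

A small end-to-end synthetic run (8 stations, 2 communities, +0.5 ppb
injected climate signal):

```r
rep <- run_pipeline(oz_config(seed = 1, n_stations = 8, n_days = 20,
                              n_communities = 2, years_health = 1998:2000,
                              n_iter = 1000, burn_in = 300, n_draws = 50,
                              lags = "dl02", signal_ppb = 0.5))
print(rep)
#> -- Exposure projection --
#> Exposure change: 0.642 ppb (95% PI 0.215, 1.069); reference 52.4 -> future 53.1 ppb
#> observed reference-period community mean: 52.4 ppb
#> calibrated reference-period predicted mean: 52.4 ppb
#> injected climate signal: 0.50 ppb
#>
#> -- Attributable deaths (baseline N = 4395, 10 years) --
#>   dl02: Attributable deaths over 10 year(s): 81.0 (95% CI -85.22, 247.2)
```

The projection recovers the injected signal up to end-to-end noise (0.64 vs
0.50 ppb at this deliberately small size), the calibrated reference
prediction reproduces the observed community mean, and the wide CI reflects
the low power of a 2-community mortality design. Larger configurations
(e.g. 19 communities) tighten everything; see the methods vignette
(`vignettes/ozone-mortality-methods.Rmd`) for model details, defaults and
limitations.

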