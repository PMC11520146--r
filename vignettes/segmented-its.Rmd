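---
title: "Segmented quasi-Poisson analysis of an interrupted weekly participation series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented quasi-Poisson analysis of an interrupted weekly participation series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkrunITS)
```

## The problem

parkrun organises free weekly 5 km events every Saturday. Weekly finisher
counts, aggregated to small English census areas (LSOAs, 1,000–3,000
residents each), grew near-linearly from 2015 until every event in mainland
England was cancelled between 21 March 2020 and 24 July 2021. The question
this package addresses is what that shutdown did to participation: the
immediate drop when events returned, the change in the growth trajectory
afterwards, how both vary across quintiles of the Index of Multiple
Deprivation (IMD), and how many finishes were lost relative to a world in
which the shutdown never happened.

The design is an interrupted time series (ITS): the pre-shutdown trend,
extrapolated forward, serves as the counterfactual, because no concurrent
control group exists for a nationwide interruption.

## The model

For a stratum (an IMD quintile, or the whole population) with constant
resident population $P$, the weekly finish count $y_w$ is modelled with a
log link and a quasi-Poisson variance:

$$
\log \mathbb{E}[y_w] = \log\frac{P}{1000}
  + \beta_0 + \beta_1 t_w + \beta_2 t_w^2
  + \lambda_w \beta_3
  + \sigma_w \left(\beta_4 + \beta_5 T_w + \beta_6 T_w^2\right)
  + \gamma_{s(w)},
\qquad \operatorname{Var}[y_w] = \phi\, \mathbb{E}[y_w].
$$

* $t_w$ is time since the window start, measured in **years** (weeks /
  52.1775). The paper-style report gives per-year rate ratios, and on this
  scale $e^{\beta}$ *is* the per-year rate ratio; a weeks-scale fit with
  $RR_{\text{year}} = \exp(52.1775\,\beta_{\text{week}})$ is numerically
  identical.
* $\lambda_w$ indicates the shutdown gap ($[\,$2020-03-21, 2021-07-24$\,)$),
  $\sigma_w$ indicates the post-reopening era (date $\ge$ 2021-07-24), and
  $T_w$ is years since reopening (0 before). $\lambda_w \sigma_w = 0$ always.
* $\gamma_{s(w)}$ is a 13-level seasonality effect: the year is cut into
  four-week blocks anchored at 1 January, with level 13 absorbing the final
  29–30 days; level 1 is the reference. Seasonality is therefore
  multiplicative on the count scale.
* The offset $\log(P/1000)$ makes $e^{\text{linear predictor}}$ a weekly
  rate per 1000 residents, the natural outcome scale when strata have very
  different populations.
* The quadratic terms let growth damp over time (an S-curve rather than
  unbounded exponential growth) and let the post-reopening recovery
  accelerate or decelerate.

Separate models are fitted per quintile and for the total, so every effect
is free to differ by deprivation.

### Why the gap coefficient is not estimated

Every count inside the gap is exactly zero, so the maximum-likelihood
estimate of $\beta_3$ is $-\infty$ (perfect separation) and an IRLS fit
chasing it would diverge. `fit_quasipoisson()` instead drops gap rows from
estimation and reports the gap effect as *not estimable*. This is not an
approximation: because $\lambda$ is 1 exactly on the dropped rows and 0
elsewhere, the profile likelihood for all remaining coefficients is
identical, which the test suite asserts by comparing against a fit that
keeps the gap rows with the gap effect pinned at $-20$ on the log scale
(coefficients agree to $10^{-6}$).

### Dispersion and intervals

Weekly counts are strongly overdispersed (weather cancellations, holidays),
so a quasi-Poisson variance $\phi\mu$ is used. $\phi$ is the Pearson
estimate $\sum r^2_{\text{pearson}} / (n - p)$, the covariance is scaled by
it, and 95% intervals are Wald intervals $e^{\beta \pm 1.96\,SE}$ — the
default of standard quasi-Poisson implementations. Point estimates are
unaffected by $\phi$.

Fitting is ordinary IRLS (`stats::glm`, quasi-Poisson family) with a
relative-deviance tolerance of $10^{-8}$ and at most 100 iterations; the
test suite cross-checks coefficients on small instances against a generic
quasi-Newton maximisation of the Poisson log-likelihood.

## Counterfactual and lost finishes

`predict_counterfactual()` evaluates three curves per week:

* `expected_count`: the no-interruption counterfactual — indicators set to
  zero, full seasonality and offset retained. On pre-gap weeks this equals
  the ordinary fitted value by construction.
* `expected_trend`: the same curve with the seasonal multiplier replaced by
  the mean of $e^{\gamma_\ell}$ over the 13 levels, weighted by how many
  weeks each level contributes — the smooth "ignoring seasonal variation"
  line. Averaging multiplicatively-entering terms arithmetically on the
  count scale is a choice; the weighting makes the averaged curve integrate
  to (approximately) the seasonal one over a year.
* `fitted_post`: the post-reopening trend on the same season-averaged scale,
  zero before reopening.

`lost_finishes()` sums counterfactual and observed counts over half-open
periods (membership by Saturday date): by default the gap
$[\,$2020-03-21, 2021-07-24$\,)$ and the post-reopening period up to
2023-03-01, plus their union. Period differences are computed as sums of
weekly shortfalls, so they are *exactly* additive and partition-consistent.
Counterfactual totals are kept as reals and rounded only for display.
`weekly_average_shortfall()` divides a period's difference by its recomputed
Saturday count rather than trusting any externally quoted week count.

`crossover_week()` finds the first post-reopening Saturday where the
season-averaged post trend reaches the counterfactual trend, i.e. the first
$T \ge 0$ with $\beta_4 + \beta_5 T + \beta_6 T^2 \ge 0$ — seasonality
cancels from the comparison, mirroring the smooth-curve presentation. The
scan covers 5 years past reopening by default; beyond that the quadratic
extrapolation is not credible anyway.

## The synthetic-data generator

`simulate_series()` draws weekly counts from exactly the mean structure
above, with gap means forced to zero, using a gamma-Poisson (negative
binomial) mixture with mean $\mu_w$ and variance $\phi\mu_w$ (size
$\mu_w/(\phi-1)$; Poisson when $\phi = 1$). Quasi-Poisson specifies only a
variance function, not a distribution; the gamma-Poisson is the standard
generative stand-in with that variance. Strata differ only in baseline and
population, mirroring the near-proportional quintile curves seen in real
data, and the `"total"` series is the exact sum of the strata.

`make_default_scenario()` is the canonical fixture: 425 weeks from
2015-01-03 (through 2023-02-18), the English shutdown dates, $\phi = 3$,
and effect sizes whose per-year rate ratios equal the total-population
point estimates of the real analysis (1.34, 0.98, 0.71, 0.76, 1.21).
Baselines not determined by those estimates were chosen once as realistic
magnitudes: five strata of 11.3 million residents (England ≈ 56.5M), week-0
rates 0.35–1.50 finishes per 1000 ordered by quintile (≈ 50,000 total weekly
finishes in early 2015, and ≈ 130,000 counterfactual weekly finishes during
the gap, the observed order of magnitude), and mild seasonal multipliers
(0.88–1.06) with a late-December trough.

What the generator deliberately does **not** emulate: LSOA-level
micro-structure (counts are drawn at stratum level), week-to-week
autocorrelation beyond what the trend and seasonality induce, weather-driven
event cancellations (real dispersion partly comes from whole events
vanishing for a week), and drift in population or deprivation. Passing
recovery tests therefore show that the estimator is correct *for the model
it assumes*, not that the model captures every feature of real
participation data.

## Numerical and design choices

* **Week grid**: all events are Saturdays, so week $k$ is the $(k+1)$-th
  Saturday on/after the window start; counts attach to their Saturday date.
* **Degenerate inputs**: all-zero model columns (e.g. a step indicator in a
  window that never reaches the reopening) raise a rank-deficiency error
  naming the column; non-convergence returns the partial fit with a
  warning and a `converged = FALSE` flag.
* **Season levels absent from the estimation window** are dropped from the
  factor rather than producing aliased coefficients; their multiplier is
  taken as 1 (the reference) in counterfactual prediction.
* **Identifiability caveat**: with only one calendar year of data each
  season level lies entirely before or entirely after an interruption, and
  the step is collinear with seasonality; at least two years spanning the
  interruption are needed, as in the study window.
* **Display**: rate ratios and intervals to 2 decimal places, percentages
  to 1, totals rounded at display only.

## Worked example

```{r, eval = FALSE}
cfg <- make_default_scenario(seed = 7)
sim <- simulate_series(cfg)
total <- subset(sim$series, stratum == "total")
fit <- fit_quasipoisson(build_design(total, interruption_config()))
rate_ratio_table(fit)
cf <- predict_counterfactual(fit)
lost_finishes(cf)
crossover_week(fit)
```

The pipeline wrapper `run_pipeline(run_config(make_default_scenario(),
out_dir = "out", seed = 1))` runs the same analysis for all six strata and
writes the rate-ratio table, period summary, residual summary, fit JSON,
both figures and a manifest.

## Problem sizes and validation

The test suite validates, among other properties: coefficient agreement
with a brute-force likelihood oracle to $10^{-6}$ on instances of up to 50
weeks and 4 parameters; Pearson dispersion near 1 on Poisson data (400
weeks); parameter recovery on the canonical scenario over 200 replicates
(absolute bias below 0.02 on the rate-ratio scale, Wald coverage at least
90%); exact additivity of the lost-finish accounting; gap-row equivalence;
and byte-exact reproducibility of the simulator and of pipeline tables
under a fixed seed. Mean-correctness of the generator is spot-checked over
1,000 replicates of a 60-week configuration.

## Limitations

The counterfactual inherits every ITS caveat: secular shocks after 2020
(e.g. cost-of-living pressure) are attributed to the interruption, the
14-month gap makes the extrapolated quadratic trend genuinely uncertain,
and aggregated data precludes any individual-level statement. The
quadratic post-trend should not be extrapolated far beyond the observed
window — the crossover date is a model summary, not a forecast. Wald
intervals ignore residual autocorrelation; the residual diagnostics report
the lag-1 autocorrelation so users can judge whether that matters for
their data.
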