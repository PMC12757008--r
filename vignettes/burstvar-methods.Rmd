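---
title: "A hierarchical bivariate VAR for measurement-burst daily data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical bivariate VAR for measurement-burst daily data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstvar)
```

## The problem

Intensive longitudinal studies of well-being increasingly pair a brief
evening self-report with continuous wearable sensing.  The design this
package targets is a *measurement-burst* cohort: each participant
contributes several two-week windows of daily measurement (here bursts at
months 0, 4, 8 and 12 after a person-specific entry date), with months of
no measurement in between.  The two daily outcomes are

* **LS** — life satisfaction, the mean of two 0–100 slider items answered
  in the evening, and
* **PA** — physical activity, summarized as *steps per valid wear-hour*:
  total wake steps divided by hours of valid device wear that day.

The scientific questions are dynamic: does yesterday's activity predict
today's satisfaction (and vice versa), how strong is the *same-day*
coupling of the two, and is that coupling stronger for people whose
self-concept includes being an exerciser (exercise identity)?

## Preprocessing

A device minute counts as **valid wear time** if it records a non-zero
step count *or* a heart-rate reading; minutes flagged as sleep are always
excluded.  Daily PA is the ratio of wake steps over valid minutes to wear
hours; a day with zero valid minutes has no PA value.  Daily LS is the
mean of the two items; by default a day with only one answered item is
treated as missing (the measure is defined as a two-item average), with a
configurable fallback.  No minimum-wear-hours floor is imposed by default;
`build_daily(min_wear_hours =)` exists for sensitivity analyses.  Days are
calendar days (midnight to midnight), the usual daily-aggregation
convention for wrist-worn trackers.

Both outcomes are bounded or skewed, so they are transformed before
modeling:

* LS: shift by one and divide by 102 — mapping [0, 100] strictly inside
  (0, 1) — then logit.  `transform_ls(50)` is exactly 0.
* PA: add one (so zero activity maps to zero) and take the natural log.

Both transforms are strict bijections with exact inverses; the package
round-trips them to machine precision.

## The model

Let \(L_{it}\), \(P_{it}\) denote the transformed outcomes of person
\(i\) on day \(t\).  The model is a first-order vector autoregression
around a covariate-driven mean with person random intercepts:

\[
\binom{L_{it}}{P_{it}} = \binom{\mu_{L,it}}{\mu_{P,it}}
 + \binom{m_{L,i}}{m_{P,i}}
 + B\left[\binom{L_{i,t-1}}{P_{i,t-1}} - \binom{\mu_{L,i,t-1}}{\mu_{P,i,t-1}} - \binom{m_{L,i}}{m_{P,i}}\right]
 + \binom{\varepsilon_{L,it}}{\varepsilon_{P,it}}
\]

with \(B = \bigl(\begin{smallmatrix}\beta_{LL} & \beta_{LP}\\
\beta_{PL} & \beta_{PP}\end{smallmatrix}\bigr)\); diagonal entries are
day-to-day autoregressions, off-diagonals cross-lagged effects (row =
target, column = source: \(\beta_{LP}\) is the effect of yesterday's
activity on today's satisfaction).

The mean \(\mu_{\cdot,it} = \delta_0 + \sum_k \delta_k X_{ik}\) carries an
intercept, day-in-study (days since that person's own first study day —
participants enter continuously), age, and indicators for gender (vs
female), region (vs the low-pollution region), weekday (six effects vs
Monday), month (eleven effects vs January), university education, and
socioeconomic status (two effects vs "below average").  The weekday and
month sets are saturated indicator submodels — periodicity is modeled
flexibly at two time scales rather than with harmonics.

Disturbances are bivariate normal with SDs \(\sigma_L, \sigma_P\) and a
**moderated contemporaneous correlation**
\(\rho_i = \tanh(\alpha_0 + \alpha_1\,\mathrm{EXID}^{std}_i)\): the
inverse Fisher-z link keeps \(\rho\) inside \((-1, 1)\) for any real
coefficients.  Exercise identity enters standardized, so \(\alpha_0\) is
the link-scale correlation for a person of *average* exercise identity and
\(\alpha_1\) is the shift per SD of identity.  Random intercepts
\(m_{L,i} \sim N(0, \tau_L^2)\), \(m_{P,i} \sim N(0, \tau_P^2)\) are
uncorrelated; they are the only link between a person's bursts — the
day-level Markov chain is *not* propagated across the months-long gaps.
The first day of each burst therefore follows the stationary distribution
of the VAR centered at \(\mu + m\), whose covariance solves the discrete
Lyapunov equation \(S = BSB^\top + \Sigma_\varepsilon\)
(`stationary_covariance()`).  An alternative treatment that conditions on
burst-first days (dropping their marginal term) is available via
`fit_bvar(first_day = "condition")`; the default uses the stationary
marginal because the stationarity-restricted prior makes it well defined
and it retains the information in first days.

## Priors

Transition entries have uniform priors on \((-1, 1)\) — the elementwise
stationarity bounds; the sampler additionally refuses (and counts) states
whose spectral radius reaches 1, where no stationary distribution exists.
Regression and \(\alpha\) coefficients have flat priors with no range
restriction; samplers that require a proper posterior use a wide-normal
fallback (SD 50 by default, `prior_config(coef_sd =)`).  The SDs
\(\sigma_\cdot, \tau_\cdot\) have half-normal priors.  Their scale is a
package choice: on the transformed-response scales the daily and
person-level SDs are of order 0.4–1.3, and a half-normal with scale 2 is
close to flat over that whole range, matching the flat-prior spirit of the
model; scale 1 would already shrink a \(\tau\) near 1.2 noticeably.  The
prior-sensitivity analysis (`prior_sensitivity()`) refits with all
half-normal scales halved and doubled and reports the correlation of
posterior-mean vectors and per-parameter shifts.

## Estimation

All parameters — coefficients, dynamics, variances, correlation-link
coefficients, random intercepts, and a latent value for every missing
response — are estimated jointly by MCMC (`fit_bvar()`).  The sampler is a
**blocked Gibbs sampler** written for this model:

1. latent missing responses are drawn from their bivariate-normal full
   conditionals (full-information estimation under missingness at random);
2. the full coefficient block (both responses jointly) is drawn from its
   multivariate-normal conditional with the random intercepts analytically
   marginalized — this partial collapsing removes the strong
   coefficient–intercept coupling that otherwise slows mixing for sparse
   indicator cells;
3. random intercepts are drawn from conjugate bivariate normals;
4. \(\beta\) entries, \(\sigma\)s and \(\alpha\)s are updated by
   stepping-out slice sampling on their scalar full conditionals
   (likelihood evaluated over all person-days);
5. \(\tau\)s are slice-updated against the random-effect density and their
   half-normal prior.

Slice sampling needs no tuning and accepts every update, so the sampler
family has no divergent transitions; `diagnose()` reports
`n_divergent = 0` structurally, alongside the count of slice evaluations
rejected for non-stationarity.  The `mcmc_config()` fields
`target_accept` and `max_treedepth` are recorded for interoperability with
gradient-based backends but are inert here.  Chains are overdispersed at
initialization (moment-based centers with random jitter) and every random
draw flows through R's RNG, so a fit is byte-reproducible given its seed.

Convergence is monitored with split rank-normalized \(\widehat{R}\)
(maximum of the bulk and folded statistics) and bulk effective sample
size (rank-normalized split chains with Geyer's initial monotone positive
sequence), the modern forms of both diagnostics.

Covariates are standardized before sampling (continuous ones: day in
study, age, exercise identity; indicators stay 0/1) and coefficient draws
are rescaled to the original covariate scale afterwards
(`rescale_coefficients()`): slope over SD, intercept absorbing the
centering, so the fitted linear predictor is invariant draw by draw.  The
standardization constants live in the dataset codebook, which is also what
makes the rescaling exactly reproducible later.

## The synthetic-data generator

The study's raw data are restricted, so the package ships a generator
that emulates the design end to end and gives every stage a ground-truth
oracle:

* **population** — two-region adult cohort, 46.3% women, 57% in the
  high-pollution region, runner-enriched (56.8%), SES roughly
  2.5/80/17.5, ages 18–65 (truncated normal, mean 38.1, SD 12.55), and an
  exercise-identity score (9–63) distributed higher for runners;
  at very small n the generator deterministically guarantees each declared
  categorical level at least one member so the design matrix keeps full
  column rank (`participant_config(ensure_levels)`);
* **calendar** — continuous entry over a multi-year window (so the month
  indicators are populated), bursts at fixed offsets from entry;
* **latent dynamics** — the exact model above, default truth
  `true_parameters()`: autoregressions 0.394 and 0.316, negligible
  cross-lags, \(\sigma\) = 1.2342 / 0.5855, \(\tau\) = 1.1847 / 0.387,
  \(\alpha_0\) = 0.0872 (correlation ≈ 0.087 at average identity),
  \(\alpha_1\) = 0.0105 per SD, weekend-peaked weekly and summer-peaked
  annual mean profiles;
* **measurement** — daily step totals spread over worn minutes by a
  multinomial draw (so zero-step worn minutes with heart-rate readings
  exercise the wear rule's second branch), a configurable sleep block,
  truncated-normal daily wear, and two integer slider items split
  symmetrically around the target mean;
* **missingness** — missing-at-random masking whose probabilities can
  depend only on observed quantities (weekday, covariates); the
  configuration schema cannot express dependence on the masked value, so
  the MAR contract holds by construction.

What the generator does *not* emulate: intraday EMA prompts (only the
evening survey exists), air-pollution concentrations (region is a binary
proxy), device idiosyncrasies, and non-MAR missingness.  Passing tests on
synthetic data therefore validate the estimator and pipeline, not the
substantive conclusions one would draw from real measurements.

Two points deserve emphasis.  First, the instrument is discretizing:
integer slider items and boundary clipping at 0/100 inject measurement
error that the model does not represent.  Its effect is real — about half
a percent of marginal SD on the logit scale, enough to attenuate
\(\sigma_L\) by roughly 2% — and visible in `recovery_study(observation =
"rendered")`.  Because a parameter-recovery study is meant to test the
estimator against data from its own model, the recovery harness defaults
to the exact latent scale (`build_latent_dataset()`); the rendering layer
is verified separately by round-trip tests with explicit tolerances
(LS within 0.5 slider units, PA within 1% relative).  Second, the two
LS items' covariation is not specified by the measure (only their mean is
used), so the generator uses a mean-preserving symmetric integer offset.

## Numerical choices

* Stationary covariances solve the 2×2 Lyapunov equation by the
  \((I - B \otimes B)\) vec-system; residuals are at machine precision.
* Degenerate conditional precisions (possible only on near-empty datasets
  where a block is informed solely by the weak prior) get a tiny ridge
  before factorization, with an informative error if that fails.
* Exactly constant draw sequences report \(\widehat{R} = 1\) and an
  undefined ESS rather than NaN; a single chain reports \(\widehat{R}\)
  as undefined.
* An effect is labelled *credible* when its central 95% interval excludes
  zero; no multiplicity adjustment is applied.

## Problem sizes used by the tests

The test suite and the acceptance script run scaled-down versions of the
analyses: the sensitivity and convergence checks use 60 persons × 2
bursts × 10 days (about 1200 person-days); sensitivity refits use 4
chains × 4000 sampling iterations because the 0.9999-correlation
comparison requires posterior-mean Monte Carlo error far below 10⁻⁴ of
the parameter spread; the convergence fit uses the default 4 × 1000/1000;
the recovery study runs 20 replicates of the full design (150 persons ×
4 bursts × 14 days) with 2 × 400/400 chains per replicate.  These sizes
were chosen so each study is statistically decisive for the property it
checks.

## Limitations

Only first-order dynamics and a time-constant transition matrix are
supported; the disturbance covariance admits no moderator other than
exercise identity; missingness is assumed MAR throughout; and
reproducibility is guaranteed per seed and package version, not across
linear-algebra backends.
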