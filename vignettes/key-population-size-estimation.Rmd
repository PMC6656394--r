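---
title: "Small-area estimation of key-population sizes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of key-population sizes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpsae)
```

## The problem

HIV programme planning needs the number of key-population members — here,
gay men and other men who have sex with men (MSM) — in every subnational
area, but survey-based size estimates exist only in a handful of cities
where community infrastructure makes sampling feasible. `kpsae` implements a
full inferential chain for this setting: multiplier-method direct estimation
from respondent-driven sampling (RDS) surveys, a heteroscedastic regression
that extrapolates the estimated population *fraction* to unsurveyed areas, a
spatial Gaussian process that imputes a missing covariate (HIV prevalence),
and a joint hierarchical Bayesian model so that every source of uncertainty
— sampling noise in the direct estimates, regression-parameter uncertainty,
and imputation uncertainty — propagates into the final prediction intervals.

The package ships a packaged table of 19 published multiplier estimates for
five departments of Côte d'Ivoire (`civ_direct_estimates()`) and a
synthetic-data generator that reproduces the statistical structure of that
study, so every stage is testable end to end without the restricted survey
records.

## Direct estimation: RDS-II and the multiplier method

A programme log gives a total count $T$ of population members enrolled at a
source (an NGO membership list, a clinic, a social event, a unique-object
distribution). An independent RDS survey estimates the proportion $\hat p$
of the population covered by that source. Because RDS reaches respondents
with probability roughly proportional to their personal network size $d_i$,
the RDS-II (Volz–Heckathorn) estimator weights by inverse degree:

$$\hat p = \frac{\sum_i b_i / d_i}{\sum_i 1/d_i}, \qquad
  \hat N = T / \hat p,$$

with $b_i \in \{0,1\}$ the reported source membership. Confidence intervals
for $\hat p$ use a nonparametric percentile bootstrap over respondents
(default 1,000 resamples); a recruitment-chain-aware bootstrap would need
the referral tree, which the downstream analysis never uses. The proportion
interval $(l, u)$ maps to the size interval $(T/u,\, T/l)$.

Zero-degree respondents are rejected at parse time rather than imputed, and
sources whose survey question was never asked are skipped. Joint
capture–recapture across sources is out of scope: the overlap between
source lists is unknown.

## The extrapolation regression

For area $i$ with male 18–29 population $N_i$, each direct estimate
$n_{ij}$ becomes a log fraction $y_{ij} = \log(n_{ij}/N_i)$, modelled as

$$y_{ij} \sim N\!\big(\beta_0 + \beta_1 \log N_i + \beta_2 H_i,\;
  \tau^2 w_{ij}\big), \qquad
  w_{ij} = \big(\log \mathrm{ci}^u_{ij} - \log \mathrm{ci}^l_{ij}\big)^2,$$

where $H_i$ is HIV prevalence in percent. The weight is the squared width
of the estimate's 95% interval on the log scale — the variance of a normal
variable is proportional to the squared width of its central interval — so
imprecise estimates are down-weighted without discarding them. The weight
depends only on the ratio of the CI bounds, so it is invariant to the
population denominator. The log (rather than logit) transform is used: the
fractions involved are small, the two transforms nearly coincide, and with
$\log N_i$ as a covariate the log scale reads directly as a relative growth
rate of the key population against the total population. Area-level random
effects are deliberately absent: with five areas they are not estimable.

Covariate selection (`rank_models()`) compares five candidates — HIV
prevalence alone, or HIV prevalence plus one of log male population, log
night-light (Landscan) density, log population density, density change —
by leave-one-area-out cross-validation: all of an area's estimates are held
out, weighted least squares (weights $1/w_{ij}$) is fitted on the rest, and
the held-out area's mean estimated fraction is predicted. The error is
measured on the fraction scale by default (`scale = "count"` is available);
the MSE is the mean over areas. With five folds this comparison is
inherently high-variance; the test suite therefore requires the generating
model to be the *modal* winner at the study's own size and an outright
$\ge 80\%$ winner only on an enlarged (16-area) design.

## The spatial model for HIV prevalence

Prevalence is observed for roughly half the areas. `kpsae` models
$H(s)$ over area coordinates $s$ (decimal degrees) as a Gaussian process
with constant mean and exponential covariance

$$\mathrm{Cov}\{H(s_i), H(s_j)\} = \sigma^2
  \exp(-\phi\, \lVert s_i - s_j \rVert),$$

with plain Euclidean distance on longitude/latitude: the study region spans
only a few degrees, a great-circle correction would be a sub-percent effect,
and the decay $\phi$ is interpreted per degree (its prior below is calibrated
to that scale). Kriging gives the conditional normal at a new location,
*including the mean correction*:

$$E[H(s) \mid H(S)] = \mu + v(s)^\top \Sigma^{-1}(H(S) - \mu 1), \qquad
  \mathrm{Var} = \sigma^2 - v(s)^\top \Sigma^{-1} v(s).$$

Two numerical conventions deserve note:

* **Variogram scale.** `empirical_variogram()` returns the plain average
  squared difference per distance bin — no factor $\tfrac12$. For GP data
  this quantity has sill $2\sigma^2$, not $\sigma^2$; the curve
  $\sigma^2(1 - e^{-\phi m})$ fitted by `fit_variogram_curve()` therefore
  estimates *twice* the GP variance on its native scale. The
  `gp_scale = TRUE` argument halves the fitted sill when the result is used
  as a GP variance estimate. The decay estimate is unaffected.
* **Maximum likelihood.** `fit_gp_mle()` profiles the likelihood: for fixed
  $\phi$, the mean has the generalized-least-squares closed form and the
  variance its plug-in estimate, leaving a one-dimensional problem in
  $\log\phi$ solved by Brent's method. This is more robust at these sizes
  than a two-dimensional quasi-Newton search. On a fixed domain only the
  product $\sigma^2\phi$ is consistently estimable for the exponential
  family; the parameter-recovery test uses a decay several times shorter
  than the domain, where the individual parameters are identifiable.
* A relative jitter of $10^{-8}$ is added to the correlation diagonal
  before every Cholesky factorization. There is no nugget term in the
  model. A prediction at an exactly observed site returns that site's value
  with variance zero.

A leave-one-out comparison (`loocv_imputation_mse()`) pits kriging against
mean imputation; on fields with genuine spatial structure kriging wins in
the large majority of replicates, and on independent fields the two tie.

## The joint hierarchical model

The regression and the GP are tied together with priors

$$\beta \sim N(0, 10^6 I), \quad \mu \sim N(0, 10^6), \quad
  \phi \sim \mathrm{Unif}(0, 10),$$
$$1/\tau^2 \sim \mathrm{Gamma}(0.01, 0.01), \quad
  1/\sigma^2 \sim \mathrm{Gamma}(2, 1) \quad \text{(shape, rate)},$$

and the joint posterior is sampled by `run_mcmc()` (default 30,000
iterations, first 15,000 discarded). The sampler is Metropolis-within-Gibbs:

* $\beta$ is drawn **jointly from its exact Gaussian full conditional**.
  A componentwise random walk is hopeless here: $\log N_i$ lives around
  10–13, so the intercept and the population slope are near-perfectly
  negatively correlated a posteriori, and componentwise proposals gave
  effective sample sizes of a few per thousand retained draws. The
  conjugate joint draw is exact and tuning-free.
* $1/\tau^2$ is conditionally conjugate,
  $\mathrm{Gamma}(0.01 + n/2,\, 0.01 + S/2)$ with $S$ the weighted residual
  sum of squares, and is Gibbs-sampled.
* $\mu$, $\sigma^2$, $\phi$ use componentwise Gaussian random walks —
  $\sigma^2$ on the log scale and $\phi$ on the logit of $\phi/10$, with
  Jacobians — whose scales adapt toward 44% acceptance during burn-in only,
  so the retained draws target the exact posterior. Only one $k \times k$
  Cholesky factorization per sweep (the $\phi$ proposal) is needed; the
  $\mu$ and $\sigma^2$ updates reuse the cached factor.

Because every training area has observed prevalence, the regression block
and the GP block are conditionally independent given the data; the sampler
still runs them in one chain so that prediction can consume a single draws
object. With no data at all the chain reproduces the priors exactly (the
conjugate blocks draw from them i.i.d.), which the test suite exploits.

Sampler validation follows a simulation-based-calibration (SBC) design on a
reduced problem (10 areas, ~2,000 iterations): parameters are drawn from
their priors, data are simulated, and the rank of each true value among
thinned posterior draws must be uniform. SBC is run for the GP block and
for the conjugate $\tau^2$ update. It is *not* run for $\beta$ under its
full prior: half of the $\mathrm{Gamma}(0.01, 0.01)$ prior mass puts
$\tau^2$ above $10^{30}$, so most prior-predictive datasets are
astronomically scaled and no short chain can mix across them — a property
of the deliberately vague priors, not of the sampler. Frequentist
calibration of $\beta$ is instead checked by a parameter-recovery study:
over 20 simulated studies at the default conditions, the 95% credible
interval covers each generating coefficient in at least 17.

## Prediction

`predict_msm()` uses composition sampling: each retained draw $m$ is pushed
through the predictive chain. For an area with observed prevalence,
$H^{(m)} = H$; otherwise $H^{(m)}$ is drawn from the kriging conditional
under $(\mu^{(m)}, \sigma^{2(m)}, \phi^{(m)})$, truncated below at zero
(prevalence is nonnegative; the GP is not). Then

$$y^{(m)} = \beta_0^{(m)} + \beta_1^{(m)} \log\max(N, t) +
  \beta_2^{(m)} H^{(m)}, \qquad n^{(m)} = N e^{y^{(m)}},$$

where $t$ is the 10% empirical quantile (linear-interpolation type) of the
population across all prediction areas. The truncation is a guard against
extrapolation: the surveyed areas are all comparatively large, so the
strongly negative population slope is not trusted below the bulk of the
population distribution. Three choices here were genuinely open and are
configurable:

* truncation affects only the covariate $\log N$; the fraction-to-count
  conversion uses the area's true $N$ (`truncate_count_N = TRUE` switches
  both);
* missing-prevalence areas are imputed independently given the observed
  field, one draw per area per iteration (`joint = TRUE` draws them
  jointly from the full conditional covariance);
* point estimates are posterior medians.

`summarize_predictions()` reports the median, the central 95% interval, the
population percentage ($100\, n/N$, exact by construction), the **relative
width** (interval width over median — the scale-free uncertainty measure
appropriate for log-normal-like quantities), and the **leverage**
$x_i^\top (X^\top X)^{-1} x_i$ of the area's covariate vector against the
training design. Two qualitative patterns are enforced by the test suite:
areas with imputed prevalence carry systematically wider relative intervals
than observed ones, and among observed-prevalence areas relative width
increases with leverage.

## The synthetic-data generator

`generate_study()` produces complete studies with the structure the
analysis assumes. Defaults are the study conditions themselves:

| quantity | default | rationale |
|---|---|---|
| areas | 61 | prediction-area count of the motivating study |
| training areas | 5 | surveyed-city count |
| estimates per area | 3–5 | methods available per city (19 total) |
| $\beta$ | $(2.62, -0.79, 0.63)$ | fitted posterior medians |
| $\tau^2$ | 0.65 | fitted posterior median |
| GP $(\mu, \sigma^2, \phi)$ | $(2.55, 0.86, 7.68)$ | fitted posterior medians (percent scale, per degree) |
| missing prevalence | 50% of areas | observed missingness (30 of 61) |
| population law | log-normal(10.3, 1.0), floor 100 | spans ~4k–350k persons, the realistic department range |
| bounding box | 8.6°W–2.5°W, 4.3°N–10.7°N | approximates Côte d'Ivoire |
| log CI half-width | Unif(0.13, 0.58) | reproduces published CI ratios 1.3–3.2 |

Training areas are spread over the upper population range — from roughly
the 36th percentile to the maximum — matching the real design, where the
smallest surveyed city sat at the 36th population percentile and the
largest was the biggest city in the country. This preserves the
extrapolation pathology that motivates truncation while giving the training
set its realistic order-of-magnitude population spread. The auxiliary
density covariates are generated with strong log-scale correlation to
population (about 0.8), as population-based measures are in practice, while
density change is pure noise and serves as the irrelevant-covariate
control. Under these defaults roughly four of five generated fractions fall
below 0.05, matching the published regime.

An RDS generator (`generate_rds_population()`) builds hidden populations
with shifted-Poisson degrees (mean 10), memberships assigned independently
of degree, and respondents sampled without replacement with probability
proportional to degree — the inclusion regime RDS-II assumes. At 2,000
respondents from a population of 20,000 the multiplier pipeline recovers
the true size within a few percent.

What the generator does **not** emulate: recruitment-tree topology (so
chain-level RDS variance is untested), violations of the source-independence
assumption behind the multiplier method, non-stationary or covariate-driven
prevalence surfaces, and areal (polygon-level) rather than point-referenced
geography. Passing tests therefore demonstrate internal consistency of the
inferential machinery under the model's own assumptions, not robustness to
their failure on real data.

## Problem sizes used by the test and acceptance suites

All stochastic checks fix their seeds. The suite runs the full pipeline at
reduced chain lengths chosen so that Monte Carlo error is small relative to
the tolerances being asserted: parameter recovery uses 20 studies at 5,000
iterations; end-to-end coverage uses 20 studies at 3,000 iterations (1,220
area-level intervals pooled); SBC uses 100 replicates at ~2,000 iterations;
the imputation comparison uses 50 fields of 31 sites; prior recovery uses a
60,000-iteration chain. `scripts/acceptance.R` recomputes the headline
quantities (RDS recovery error, imputation MSEs, posterior medians,
coverage rates, width ratios) from scratch at the same scales.

## Known limitations

* The multiplier method inherits the independence assumption between
  programme logs and the RDS survey; if enrolment and survey participation
  correlate, direct estimates are biased and everything downstream follows.
* Multiple estimates within an area are treated as independent given area
  covariates; shared survey machinery makes them positively correlated in
  truth, so reported intervals for training areas are, if anything, narrow.
* The bootstrap CI for the RDS-II proportion ignores the recruitment chain.
* Population truncation is a heuristic guard, not an estimated change
  point; predictions for the smallest areas equal the at-threshold
  prediction by construction and should be read as such.
* The exponential covariance and constant GP mean are parsimonious choices
  for ~30 observed sites; with richer data a Matérn family or trend terms
  would be natural next steps.
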