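---
title: "Combining imperfect data sources to estimate and forecast disaggregated prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining imperfect data sources to estimate and forecast disaggregated prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevfuse)
```

## The problem

Health agencies often need prevalence estimates — and forecasts — broken
down by age, sex, region and urban–rural residence, but no single data
source supports that level of detail. Household examination surveys are
close to unbiased but sparse: a handful of rounds, small samples per
cell, some ages missing in some rounds. Administrative sources (for
example school health records) are dense in space and time but cover only
part of the population and measure with error, typically with biases that
vary by age. prevfuse implements a Bayesian framework that treats the
true prevalences as a latent process, attaches an explicit measurement
model to each observed source, and infers everything jointly, so that
interpolation of past gaps and forecasting of future years are the same
operation.

## The system model

For age $a$, sex $s$, region $r$, urban–rural class $u$ and year $t$, the
latent true case count follows a binomial law over the known population
at risk,
$$y^{\mathrm{True}}_{asrut} \sim \mathrm{Binomial}(\pi_{asrut},\,
n^{\mathrm{True}}_{asrut}),$$
and prevalence is modelled on the logit scale as a noisy linear predictor,
$$\operatorname{logit}(\pi_{asrut}) \sim N(x_{asrut}\beta,\ \sigma^2).$$
The effect vector $\beta$ contains an intercept, main effects for every
classification dimension, and age–sex, age–time and sex–time
interactions. Each term carries one prior family:

* intercept $N(0, 10^2)$; age, sex and age–sex effects $N(0, 1)$;
* exchangeable region and urban effects $N(0, \tau^2)$ with half-normal
  priors (sd 1) on the hierarchical sds;
* time-bearing terms get a damped linear trend: the year level
  $\beta_t = \alpha_t + \varepsilon^\beta_t$, level
  $\alpha_t = \alpha_{t-1} + \delta_{t-1} + \varepsilon^\alpha_t$, drift
  $\delta_t = \phi\,\delta_{t-1} + \varepsilon^\delta_t$, with
  half-normal (sd 1) priors on the three innovation sds and
  $(\phi - 0.8)/0.2 \sim \mathrm{Beta}(2, 2)$, so $\phi \in [0.8, 1]$.
  The age–time interaction gives each age its own level/drift chain but
  shares the variance and damping parameters across ages; the sex–time
  interaction uses the same damped family (the damping assumption for
  this term is a design choice made for uniformity — an undamped local
  linear trend is the $\phi = 1$ boundary of the same family).

Damping matters for forecasting: drifts are shrunk towards zero at rate
$\phi$ per year, which tempers long-run extrapolation without forcing
rates of change to be constant.

Two identifiability choices are ours. First, non-time terms (age, sex,
region, urban, age–sex, and the panel model's country and country–sex
terms) are constrained to sum to zero within each margin, which removes
additive aliasing with the intercept; time-bearing interactions are left
unconstrained because exact cross-age constraints are incompatible with
independent per-age trend chains, and all priors are proper so the
posterior is too. Second, the initial level and drift of every trend
chain get weakly informative $N(0, 1)$ priors.

## Data models

Each source is linked to the latent process by its own measurement model;
the likelihood of all sources is the product of the per-source
likelihoods.

* **Design-based survey estimates** (counts with known standard errors):
  $y^{\mathrm{Est}}_{ast} \sim N\!\big(\sum_{r,u} y^{\mathrm{True}}_{asrut},\,
  \kappa_{ast}^2\big)$, with $\kappa$ supplied by the survey's
  design-based estimation. A source that does not record sex is compared
  with counts aggregated over sex as well. Missing cells simply
  contribute nothing.
* **A single survey modelled without a measurement layer** (used for the
  sparse single-source model and for the international panel): effective
  counts $(y^{\mathrm{eff}}, n^{\mathrm{eff}})$ enter a continuously
  extended binomial likelihood on the cell prevalence directly. Effective
  counts are the raw counts divided by the design effect:
  $n^{\mathrm{eff}} = \hat p(1-\hat p)/\widehat{\mathrm{var}}(\hat p)$ and
  $y^{\mathrm{eff}} = \hat p\, n^{\mathrm{eff}}$, which reproduces the
  design-based mean and variance under a simple-random-sampling working
  model. Boundary estimates $\hat p \in \{0, 1\}$ must be clamped to
  $[1/(2n), 1 - 1/(2n)]$ using the known raw size first.
* **Administrative counts**: on the log scale with an age-specific
  multiplicative bias,
  $\log y^{\mathrm{Est}}_{asrut} \sim N(\log y^{\mathrm{True}}_{asrut} +
  \gamma_a,\ \varsigma_y^2)$, $\gamma_a \sim N(0, \varsigma_\gamma^2)$.
  Bias varies only by age: with one subnational source there is no way to
  distinguish regional coverage differences from regional prevalence
  differences, and more flexible data models destabilise the fit.
  $\varsigma_y$ and $\varsigma_\gamma$ default to half-normal (sd 1)
  priors; $\varsigma_y^2$ can instead be given a scaled
  inverse-chi-squared prior (see calibration below).

## Informative hyperpriors from an international panel

Sparse national time series say little about plausible year-to-year
variability, which is exactly what drives forecast width. The package
fits the same damped-trend model to a cross-country panel of prevalence
estimates (converted from point estimates and 95% intervals to effective
counts by inverting a normal approximation), discards everything except
the posterior samples of the year-trend hyperparameters
$(\tau_\beta, \tau_\alpha, \tau_\delta, \phi)$, and approximates those
samples by closed-form hyperpriors: half-normals by matching
$E[x^2]$, and a Beta on the rescaled damping parameter by matching mean
and variance. Moment matching is used rather than quantile or divergence
fitting because it is closed-form and reproducible. Because smoothed
panel series understate real year-to-year variation, the default inflates
the approximated variances by a factor of 2 (holding the Beta mean
fixed); factors 1 and 4 are the sensitivity variants. Only rates of
change are pooled this way — absolute levels remain anchored by the
domestic data.

## Calibrating the administrative error variance

A half-normal prior on $\varsigma_y$ favours values near zero, which in a
data model means treating administrative noise as real variation. The
package derives a prior with mass away from zero from the administrative
direct estimates themselves: approximate log true prevalence by the
system model's main effects and interactions (the age bias is absorbed
into the age effect), fit by ordinary least squares, and use the residual
variance as the scale of a scaled inverse-chi-squared prior
(default df 30, scale rounded to 3 decimals). With df 30 and scale-squared
0.015 the implied central 95% interval for $\varsigma_y^2$ is
(0.010, 0.027):

```{r}
central_interval(prior_scaled_inv_chisq(30, 0.015), 0.95)
```

The residual variance deliberately over-counts — it absorbs the
cell-level noise $\sigma$ and any curvature the log-linear approximation
misses — so it should be read as an upper anchor for the plausible range,
not an unbiased estimate of $\varsigma_y^2$.

## Posterior computation

All unknowns — effects, trend states, hyperparameters, latent true
counts, data-model parameters, and prevalences over every cell including
forecast years — are sampled jointly by a Gibbs/Metropolis hybrid written
for this model:

* vectorised elementwise random-walk Metropolis for cell
  logit-prevalences (conditionally independent given the latent counts);
* a compiled sequential sweep for the continuous-relaxed latent counts,
  which are coupled across cells through aggregated survey observations,
  plus a joint (logit-prevalence, count) sweep that moves both along the
  ridge created by large exposures;
* conjugate draws for effect terms (with exact constrained-normal draws
  for sum-to-zero terms), forward-filter backward-sampling for the
  level/drift states, slice sampling for scale parameters and the
  damping parameter, and a conjugate variance draw when the
  administrative prior is scaled inverse-chi-squared;
* exact translation draws along prior-aliased directions (intercept
  versus the year level; each interaction's chain levels versus its main
  effect).

Latent counts are treated as continuous on $(0, n)$ via the log-gamma
extension of the binomial likelihood, which is what allows gradient-free
joint moves with the prevalences; with exposures in the tens of
thousands the discretisation is negligible (we verified the posterior
against an independent integer-count sampler on a small instance during
development).

Two directions of the posterior are softly identified by design, and the
sampler treats them explicitly. The cell-level noise sd $\sigma$ and the
administrative noise sd $\varsigma_y$ trade off along
$\varsigma_y^2 + c^2\sigma^2 \approx$ constant (where $c$ is the
log-scale slope), because within the administrative window both produce
the same residual dispersion; only survey overlap years and
higher-order structure separate them. Likewise each age's bias
$\gamma_a$ trades off against that age's trend level over the
administrative window, priced only by trend smoothness at the window
boundaries. Single-site samplers cross such ridges diffusively and can
appear converged at one end. The package adds orbit moves for both: a
variance-swap slice that moves $(\sigma, \varsigma_y)$ along the ridge
while transporting each administrative cell's prevalence through its
linearised conditional Gaussian, and a per-age translation slice for
(bias, window trend level). Both families are one-parameter groups, so
slice sampling along the orbit with the exact joint density and the
affine volume terms is a valid update; the linearisation shapes only the
orbit, never the target. Correctness of the full sweep was checked with
a Geweke successive-conditional test (alternating parameter updates and
data regeneration leaves every parameter distributed per its prior) and
against quadrature oracles for the cell-level kernels.

Defaults are 4 chains, 1000 warmup and 1000 sampling iterations;
proposal scales adapt during warmup only. Convergence is summarised by
split-chain potential scale reduction and effective sample size with
pass thresholds 1.05 and 100. Summaries report medians and central 50%
and 95% intervals using linear interpolation of order statistics
(quantile type 7). Forecast-year cells carry no data by construction and
are drawn from the trend priors conditional on the sampled states.

## Replicate-data checks

To probe whether the model can generate the geographical variation in
trends seen in an administrative source, the package draws replicate
datasets: take $\beta^{(k)}, \sigma^{(k)}, \gamma^{(k)},
\varsigma_y^{(k)}$ from a posterior draw, generate fresh prevalences from
the prior model, fresh counts from the binomial layer, and fresh
administrative estimates from the data model, preserving the observation
mask. Each series (age–sex–region–urban combination) is summarised by
the least-squares slope of its values against year. A series is flagged
when the observed slope is more extreme than all $K$ replicates in
either direction, so under a well-specified model each series is flagged
with probability $2/(K+1)$ — exactly 5% at the default $K = 39$ (a
deliberate choice: the two-sided tail is then exact). The overall verdict
compares the flagged fraction with its binomial expectation.

## The synthetic-data generator

Because the motivating datasets cannot be redistributed, every stage is
exercised on synthetic bundles whose defaults mirror the study
conditions: 4 age groups by 2 sexes by 8 regions by urban/rural; years
1990–2029 with data to 2019, so the forecast horizon is exactly 10
years; five survey rounds (1991, 1997, 2004, 2009, 2014) with the 2004
round omitting the two youngest age groups and per-cell effective sample
size 400; one sex-aggregated round in 2001 covering only the youngest
age group; an administrative source covering 2013–2019 with true biases
$(0, -0.35, -0.5, -0.5)$ across the four age groups (near-zero for the
youngest, substantially negative otherwise) and log-scale noise sd 0.1;
cell-level noise sd $\sigma = 0.1$; known exposures of $10^5$ children
per cell; and a 40-country panel for 1990–2016 with effective size 5000
per estimate. Effect scales (intercept $-2.3$, age span $\approx 0.45$,
sex difference 0.2, region sd 0.15, urban difference 0.2, upward drift
0.04 per year with damping 0.9) were chosen once as plausible for a
childhood-obesity-style application and are not revisited.

What the generator does not emulate: real geography or school-coverage
mechanisms, individual anthropometry, survey nonresponse, or
non-stationary measurement bias. Passing recovery tests on these bundles
therefore demonstrates that the inference machinery is correct and
well-calibrated under the model's own assumptions — not that the model
is correct for any particular real dataset; the replicate-data checks
are the tool for interrogating the latter.

## Numerical choices and limitations

Variances inside the Kalman filter are floored at $10^{-12}$; slice
samplers bound scale parameters below at $10^{-9}$; boundary survey
proportions are clamped using the raw sample size; latent counts are
kept strictly inside $(0, n)$. Problem sizes in the test-suite
recovery study (ten replicates of the full 5,120-cell grid at 2 chains
of 500 warmup and 500 sampling iterations) were chosen to give stable
coverage estimates at modest cost; the same code runs unchanged at the
package defaults for real analyses.

Known limitations: the $(\sigma, \varsigma_y)$ decomposition remains
diffuse under vague priors — wide credible intervals for both are the
honest answer, and the calibrated inverse-chi-squared prior is the
remedy when an external anchor is wanted; biases varying by region
cannot be identified from a single subnational source; and exchangeable
region effects ignore spatial adjacency by design.
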