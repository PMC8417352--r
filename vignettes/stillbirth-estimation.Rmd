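---
title: "Estimating stillbirth rates from heterogeneous surveillance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stillbirth rates from heterogeneous surveillance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillbirthr)
```

## The estimation problem

A stillbirth, for international comparison, is the birth of a baby with no
signs of life at or after 28 completed weeks of gestation; the stillbirth
rate (SBR) is the number of such events per 1000 total births (livebirths
plus stillbirths). Country-year SBR observations come from very different
mechanisms — administrative registration systems, health management
information systems (HMIS), household surveys with pregnancy histories, and
population-based studies — and are reported under different viability
thresholds (28 or 22 weeks' gestation, 1000 g or 500 g birthweight, or no
stated definition at all). Rates measured under broader thresholds are
systematically higher; surveys under-report stillbirths; facility systems
may miss births outside facilities; and some sources under-count
stillbirths badly enough that the observation is worthless.

`stillbirthr` implements the full estimation chain for this setting:

1. **Quality control.** Deterministic rules exclude observations with no
   usable definition, more than 50% of stillbirths of unknown gestational
   age, livebirth registration coverage below 80% (75% for HMIS), or
   child-death registration completeness below 95%. A probabilistic test
   then screens for stillbirth under-reporting: the observed ratio of the
   stillbirth rate to the neonatal mortality rate (NMR) is compared with
   the distribution of such ratios in high-quality study data, and the
   observation is excluded when the probability of a smaller ratio is below
   0.05 (strictly).
2. **Definitional adjustment.** Rates reported under alternative
   definitions are rescaled to the 28-week standard by the expected
   alternative:GA28 ratio, with the ratio's variance propagated to the
   observation's log-scale uncertainty by the delta method.
3. **Hierarchical model.** A Bayesian hierarchical temporal sparse
   regression for the latent log rates, fitted by MCMC.
4. **Indicators.** Posterior draws are turned into rates and counts with
   90% uncertainty intervals, birth-weighted regional and global
   aggregates, annual rates of reduction, percentage changes and SBR:NMR
   ratios.

## The model

For country $c$ and year $t$, with the rate expressed as a proportion of
total births,

$$\log r_{c,t} = \mathbf{x}_{c,t}^\top \boldsymbol\beta + \alpha_c + \delta_c(t).$$

* $\mathbf{x}_{c,t}$ are six standardised covariates in fixed order:
  log NMR, log low-birthweight rate, antenatal-care (4+ visits) coverage,
  caesarean-section rate, mean years of female schooling, and log GNI per
  capita. Survey-derived coverage series (`anc4`, `csec`) are first
  smoothed per country by penalised least squares with a second-difference
  roughness penalty, the weight chosen by leave-one-out cross-validation;
  the penalty null space means constant and linear series pass through
  unchanged, gaps are interpolated and edges extrapolated linearly.
* $\boldsymbol\beta$ carries a regularised horseshoe prior: heavy-tailed
  local scales $\lambda_j \sim C^+(0,1)$, a global scale
  $\tau \sim C^+(0, \tau_0)$ with $\tau_0 = 0.05$ (a small value encoding
  an expectation of roughly two active covariates), and a slab scale of 1
  bounding how far a selected coefficient can move on the standardised
  scale. Irrelevant covariates are shrunk towards zero without being
  dropped.
* $\alpha_c$ is a country intercept with a region/world hierarchy:
  $\alpha_c \sim N(\alpha_{r(c)}, \tau_\alpha^2)$,
  $\alpha_r \sim N(\alpha_w, \tau_{\text{region}}^2)$, and
  $\alpha_w \sim N(\log 0.014, 1.5^2)$ (centred at 14 per 1000). Scale
  parameters have half-normal priors.
* $\delta_c(t)$ is a country-specific smooth deviation: a cubic B-spline
  basis on the year grid (knots every 2.5 years) whose coefficients follow
  a first-order random walk with per-country innovation scale $\tau_c$,
  itself lognormal around a shared mean — countries with strong data can
  deviate from the covariate prediction, data-poor countries shrink to it.
  Each $\delta_c$ is constrained to sum to zero over the grid so that
  $\alpha_c$ carries the level.

An adjusted observation $y_i$ (log GA28-scale rate) is modelled as

$$y_i \sim N\!\big(\log r_{c_i,t_i} + b_{\text{survey}}\,\mathbb{1}[\text{survey}],\;
v^{\text{samp}}_i + v^{\text{def}}_i + \sigma^2_{s_i}\big),$$

with a single global survey bias $b_{\text{survey}} \le 0$ (zero-truncated
normal prior, scale 0.2; surveys under-report stillbirths), binomial
delta-method sampling variance $(1-p)/(Tp)$ from counts where available
(surveys multiplied by a design effect, default 2.0) or a source-type
default otherwise, the definitional-adjustment variance, and a per-source
error scale. The administrative scale is fixed at 0.01 on the log scale to
anchor the variance decomposition; HMIS, survey and study scales are
estimated with half-normal priors.

Consequences built into this structure: point estimates track the data
where observations are precise, follow the covariates where data are absent,
and interval width decreases as data availability and precision increase.

## Posterior computation

The joint posterior couples extremely stiff directions (administrative
observations with hundreds of thousands of births pin the latent surface to
about 0.01 on the log scale) with order-one hierarchy scales and the
horseshoe's heavy tails. A single gradient-based sampler on the full joint
— including a mode-initialised, Hessian-preconditioned Hamiltonian Monte
Carlo — needs step sizes near $10^{-3}$ here and mixes too slowly to be
useful. The package therefore exploits the model's conditional structure
(`run_sbr_mcmc()`); per sweep:

1. **Linear block, exact.** Given all scale parameters the model is
   linear-Gaussian in $(\boldsymbol\beta, \alpha_w, \alpha_r, \alpha_c,
   \text{spline deviations})$; the block is drawn exactly from its
   multivariate-normal conditional via a Cholesky solve of the posterior
   precision.
2. **Survey bias, exact.** Its conditional is a zero-truncated normal,
   drawn by inverse-CDF.
3. **Horseshoe block, HMC.** $(\log \lambda_1, \dots, \log\lambda_6,
   \log\tau)$ move jointly by Hamiltonian Monte Carlo on the analytic
   gradient of their conditional, with dual-averaging step-size adaptation
   during warmup (target acceptance 0.8, 8–16 leapfrog steps).
4. **Remaining scales, slice.** The intercept-hierarchy scales, innovation
   scales, their hyper-pair and the source error scales are updated by
   univariate slice sampling (stepping-out with shrinkage), which is
   rejection-free and immune to the unbounded left-tail curvature of scale
   conditionals.
5. **Interweaving.** The centred parameterisation mixes poorly for the
   innovation-scale hierarchy (the classic funnel), so each sweep also
   re-draws every $\log\tau_c$ — and then the hyper-pair
   $(\mu_\tau, \sigma_\tau)$ — in the ancillary (non-centred)
   parameterisation with the standardised path shape held fixed. These
   ancillary conditionals see the likelihood directly and break the
   funnel.

All randomness derives from the user seed (chain $k$ uses `seed + k`), so
reruns are bit-identical. Convergence is monitored by split-$\hat R$ and an
initial-positive-sequence effective sample size on every coordinate
(`mcmc_diagnostics()`; pass thresholds $\hat R < 1.05$, ESS $> 100$ —
conventional choices). The full unconstrained log posterior and its
analytic gradient (`sbr_lp_grad()`) remain exported as the model's
contract and are verified against numerical differentiation in the tests;
a generic adaptive HMC (`run_hmc()`) is provided for free-form targets.

## The synthetic-data generator

No real input database ships with the package, so `generate_world()`
produces worlds with the statistical structure the model assumes, plus
ground truth and per-row provenance. The default world has 4 regions × 5
countries × 20 years (2000–2019), one region per World Bank income group,
so the full pipeline runs in seconds on one CPU. Its main design choices:

* **Covariates** are smooth per-country series whose levels follow the
  income gradient (e.g. NMR from ~3 per 1000 in high-income to ~30 in
  low-income settings) with wide independent country-level dispersion
  (log-sds 0.25–0.5). The dispersion is deliberate: with purely
  income-driven covariates all six columns are nearly collinear and no
  method could attribute effects to individual covariates, so the sparsity
  behaviour of the shrinkage prior would be untestable.
* **Truth** follows the model: true
  $\boldsymbol\beta = (0.5, 0.2, 0, 0, 0, 0)$ (NMR a strong predictor, low
  birthweight a moderate one, four exact zeros), intercept hierarchy scales
  0.15/0.2, random-walk spline deviations with median innovation scale
  0.05.
* **Observations** are emitted per country-year-source with
  income-dependent probabilities (administrative data dominate rich
  countries; HMIS, surveys and studies dominate poorer ones). Counts are
  drawn binomially for ADMIN/HMIS (total births from livebirths times a
  random coverage); surveys and studies get an effective sample size and
  log-scale noise. GA22 reporting occurs with probability 0.3 (high-income)
  or 0.15 (elsewhere) and multiplies the rate by the true definitional
  ratios 1.5/1.2 plus ratio noise; 5% of rows lose their definition label;
  surveys carry a −0.10 log-scale bias; a corrupt 15% of observations
  under-report stillbirths by a factor 0.5.
* **NMR truth** for the ratio test is tied to the true SBR at a true
  SBR:NMR ratio of 0.8, with a separate high-quality ratio sample
  (lognormal, log-sd 0.15) from which the reference distribution is fitted.

What passing tests on these worlds do **not** show about real data: real
covariates are measured with error and missingness far beyond the
generator's; real source biases are not exactly constant on the log scale;
real definitional ratios vary with the rate level (the package's constant
ratios mirror the published adjustment approach, which shares this
limitation); and real data gaps are more adversarial than random thinning.

## Numerical and policy choices

* Rates are stored per 1000 total births externally and converted to
  proportions internally; counts use $S = L\,r/(1-r)$ so that
  $S/(S+L) = r$ exactly; livebirths default to thousands with the unit
  recorded in the file header.
* Uncertainty intervals are 90% equal-tailed empirical quantiles
  (linear-interpolation convention), computed draw-wise *after* any
  aggregation; aggregates are birth-weighted sums of draw-level counts, so
  world = Σ regions = Σ countries holds to machine precision per draw.
* The annual rate of reduction is $\log(r_{t_2}/r_{t_1})/(t_1-t_2)$ for
  $t_1<t_2$; its intervals are draw-wise ARR quantiles (the only internally
  consistent option, since the transform is nonlinear).
* The point estimate is the posterior median, quantile-consistent with the
  log-scale model.
* The ratio-test probability integrates the reference CDF over the observed
  ratio's sampling distribution (lognormal with matching mean and CV) by
  Monte Carlo with $10^4$ draws and a fixed private seed; with zero
  standard error it reduces to the exact CDF value. The observed ratio's
  standard error combines the rate's sampling + definitional CV with the
  NMR CV by the delta method (the source publications do not state a
  combination rule).
* The packaged adjustment table carries the published GA22:GA28 means (1.5
  high-income, 1.2 low/middle-income pool); its variances and the
  birthweight-definition rows are documented placeholders meant to be
  refitted from paired data with `estimate_adjustment_ratio()`.
* Exclusion reasons have a fixed priority order; every excluded row carries
  exactly one reason, and kept + excluded always partitions the input.
* Deterministic QC runs before definitional adjustment, which runs before
  the ratio test (the test applies to 28-week and adjusted definitions).
* Observations are referenced to mid-year; the estimation window is
  [2000, 2019] by default and configurable.

## Problem sizes used in the tests

The test-suite and acceptance measurements run the default 20-country
world with 2 chains × (400–500 warmup, 600–1500 retained draws), chosen so
a full parameter-recovery study over ten worlds completes in a few minutes
on a single core; the package default is 4 chains × (1000, 1000). Interval
calibration is assessed by pooled 90%-interval coverage of the true latent
log rates over ten independently generated worlds.

## Known limitations

* The strict sparsity ordering (every null $|\beta|$ below every signal
  $|\beta|$) is fragile in 20-country worlds: the weaker 0.2 signal is only
  about two posterior standard deviations from zero, and a null covariate
  can pick up chance correlation with the country intercepts. Expect it to
  hold in most but not all worlds.
* Definitional adjustment ignores the rate level; per-country survey biases
  are not identifiable at this scale and a single global bias is used.
* Covariate measurement error is not modelled; smoothing is the only
  pre-processing.
* Counts treat livebirths as known; their uncertainty is not propagated
  (matching the reporting convention for this indicator).
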