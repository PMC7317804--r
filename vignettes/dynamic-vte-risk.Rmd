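---
title: "Joint modelling of D-dimer trajectories and time to VTE: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of D-dimer trajectories and time to VTE: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with active cancer face a high risk of venous thromboembolism
(VTE). The coagulation biomarker D-dimer, measured once at baseline, is a
known predictor of cancer-associated VTE, but cancer and coagulation are
dynamic: a biomarker trajectory observed over repeated monthly visits may
carry prognostic information that a single snapshot cannot. Quantifying that
information is statistically delicate, because the observed trajectories are
informatively censored — patients with rising D-dimer preferentially leave
the risk set through thrombosis or death, so naive longitudinal summaries of
survivors drift downward.

`jointtraj` implements the standard remedy: a **joint model of longitudinal
and time-to-event data**, together with the surrounding estimators (competing
risk cumulative incidence, baseline Weibull regression, group-specific
trajectory slopes) and individualized dynamic risk prediction, plus a
synthetic-cohort generator so the whole pipeline can be exercised and
calibrated end to end without access to patient-level data.

## The model

**Longitudinal submodel.** For subject $i$ at visit time $t_{ij}$ (days from
baseline), the observed biomarker on the model scale (log2 µg/mL by default,
so that one unit is one doubling) is

$$y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
  m_i(t) = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t + x_i'\gamma_L,$$

with $(b_{0i}, b_{1i}) \sim N(0, D)$, $D$ unstructured (random intercept and
slope may correlate), and $\varepsilon_{ij} \sim N(0, \sigma^2)$.

**Event submodel.** Time to VTE follows a Weibull proportional-hazards model
whose log hazard tracks the *current value* of the latent trajectory:

$$h_i(t) = \lambda p t^{p-1}
  \exp\{w_i'\gamma_S + \alpha\, m_i(t) + \alpha_d\, m_i'(t)\}.$$

$\alpha$ is the association parameter: on the log2 scale, $e^\alpha$ is the
hazard ratio per doubling of the latent D-dimer level at any time of
follow-up. The optional first-derivative term $\alpha_d$ (the subject's
latent slope $\beta_1 + b_{1i}$) is a sensitivity analysis. Competing death
is treated as right censoring in the event submodel; the consequence — a
mild upward tilt of absolute risk predictions — is discussed under
limitations.

**Likelihood.** The observed-data likelihood integrates the shared random
effects out of the product of the two submodels:

$$\ell(\theta) = \sum_i \log \int_{\mathbb{R}^2}
 \Big[\prod_j N(y_{ij};\, m_i(t_{ij}), \sigma^2)\Big]\,
 h_i(T_i)^{\delta_i} e^{-\int_0^{T_i} h_i(s)\,ds}\,
 N(b_i;\, 0, D)\, db_i.$$

## Numerical strategy

* **Random-effects integral.** Adaptive tensor-product Gauss-Hermite
  quadrature, 9 nodes per dimension by default. The centering and scaling
  use the *analytic* Gaussian posterior of $b_i$ given the longitudinal data
  at the currently evaluated parameters (a 2×2 closed form recomputed every
  likelihood evaluation); the survival factor's tilt is ignored in the
  centers. This makes the quadrature exact when $\alpha = 0$ — a property
  the test-suite checks as an identity (joint log-likelihood equals mixed
  model plus Weibull log-likelihoods to numerical precision) — and accurate
  otherwise (doubling the node count changes the log-likelihood of a test
  instance by well under $10^{-4}$; a 100,000-draw Monte-Carlo oracle agrees
  within sampling error).
* **Cumulative hazard.** $\int_0^{T} \lambda p s^{p-1} e^{\alpha m_i(s)} ds$
  is evaluated with a 15-node Gauss-Legendre rule after substituting
  $u = (s/T)^p$, which removes the $s^{p-1}$ singularity; for $\alpha = 0$
  the rule is then exact for any shape $p$.
* **Optimisation.** `nlminb` on an unconstrained parameterisation: log
  residual SD, log-Cholesky factors of $D$, log Weibull shape and scale.
  Starting values come from the standalone `lme4` mixed-model fit (ML) and
  the standalone Weibull fit; association terms start at 0. Convergence is
  judged by the optimizer status or, failing that, by the finite-difference
  score at the returned point.
* **Standard errors.** Inverse of a central finite-difference observed
  information (relative step $10^{-5}$) on the unconstrained scale; the
  association parameters are untransformed, so their Wald intervals are read
  off directly.

### Standing on established fits

Every standard step is delegated: the mixed model to `lme4::lmer` (ML, not
REML, so AICs are comparable across fixed-effect structures), Kaplan-Meier
and Aalen-Johansen estimation to `survival::survfit` (single-state and
multi-state), with pointwise bands on the log(−log) scale. The baseline
Weibull proportional-hazards regression is maximised directly in its PH
parameterisation (hazard ratios per unit, per 5 units, or per doubling);
`survival::survreg`, which uses the accelerated-failure-time
parameterisation, serves as an independent cross-check in the tests rather
than as the implementation. The joint likelihood itself — the package's
reason to exist — is implemented from first principles with an Rcpp kernel.

## Dynamic prediction

Given a fitted model and one patient's history $\mathcal{Y}_i(s)$ of visits
up to a landmark time $s$ (with the patient known event-free at $s$), the
conditional risk over a horizon $u > s$ is

$$\pi_i(u \mid s) = 1 - E\!\left[\frac{S_i(u \mid b_i, \theta)}
  {S_i(s \mid b_i, \theta)}\right],$$

with the expectation over the posterior of $(b_i, \theta)$. The default
scheme draws $\theta$ from its asymptotic normal and $b_i$ from a normal
approximation at the empirical-Bayes mode of
$\log p(\mathcal{Y}_i(s), T_i > s, b)$ — the mode includes the
survival-to-landmark term, which correctly pulls inferred trajectories down
relative to a purely longitudinal fit. An exact random-walk Metropolis
sampler of the conditional is available (`b_sampler = "metropolis"`); on
test cases the two agree to well within Monte-Carlo error. Pointwise bands
are Monte-Carlo percentiles. The default horizon of interest is 180 days
("6-month risk"); a month is fixed at 30 days everywhere in the package.

## The synthetic-cohort generator

No patient-level data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes, and
`paper_like_params()` fixes the study-like conditions:

| quantity | value | provenance |
|---|---|---|
| subjects | 167 | study size |
| follow-up | 250 days, visits every 30 ± 3 days, max 7 | study design |
| baseline D-dimer | lognormal, median 0.97 µg/mL | reported median |
| intercept SD (log2) | 1.4 | from the reported interquartile range |
| slope SD | 0.01 /day (log2) | assumption (see below) |
| residual SD | 0.4 (log2) | assumption |
| association $\alpha$ | 1.0225 per doubling | $\log 2.78$ |
| 250-day VTE incidence | 12% | calibrated via the Weibull scale |
| death | constant hazard, 20% by day 250 | reported death count |
| missingness | 1% per visit, completely at random | reported missingness |

The event time is drawn by inverting each subject's cumulative hazard
against an Exp(1) draw with bracketed bisection (tolerance $10^{-6}$ day); a
trapezoid-grid oracle validates the inversion in the tests. The Weibull
scale is not a free choice: it is solved by quadrature plus root bracketing
so that the *marginal* 250-day VTE incidence (cause-specific, accounting for
the competing death rate when present) hits the target — the calibration is
deterministic and part of the generator.

**What the generator does not emulate.** The real data's measurement-error
magnitude and random-effect covariance are not reported anywhere, so the
slope SD and residual SD above are assumptions chosen to give realistic
trajectory heterogeneity; treatment courses, infections, remission status
and any time-varying covariates are absent; death is an independent constant
hazard, whereas real mortality correlates with D-dimer. Passing tests
therefore demonstrate that the estimators recover the truth *under the
model's own assumptions* — internal validity — not that the model fits any
particular clinical population.

## Design decisions

* **Trajectory scale.** Simulation and default fitting are on the log2
  scale, matching the per-doubling parameterisation; the original µg/mL
  scale is supported in the same machinery. AICs across outcome scales are
  only comparable after a change-of-variable correction;
  `compare_fits(correct_jacobian = TRUE)` adds
  $2\sum_i \log|dy_i'/dy_i|$ and refuses mixed-scale comparisons without it.
  On right-skewed cohorts the log2 specification wins this comparison,
  matching the direction reported for the original analysis.
* **Preprocessing.** Exclusion of any patient with a D-dimer measurement
  above 40 µg/mL is per-patient (mirroring the original analysis rule, where
  one extreme patient prevented convergence). Values below 0.1 µg/mL are
  floored before the log transform; the threshold is a conventional
  limit-of-detection guess, as the source analysis reports no value below
  0.4. Time is stored in days; conversion to 30-day months happens once.
* **Grouping by prospective event status** (the descriptive per-group slope
  table) conditions on the future and is labelled as such; the joint model
  is the inferential product.
* **Calibration experiments fit the simulated data as generated** (no cap,
  no floor), since their generating processes put nonnegligible mass above
  40 µg/mL at n = 500 and truncating would selectively delete the
  highest-risk subjects the association is estimated from.
* **Weibull regressions censor competing deaths** (whether the original
  analysis censored or excluded them is unstated; censoring is the
  defensible default and is documented).
* **Ties** in the incidence estimators are handled events-before-censoring;
  different-cause ties share one risk-set update (inherited from
  `survival`).
* **Fatal pulmonary embolism** counts as a VTE endpoint, not a death.
* **Khorana score** is consumed as an integer covariate only. The adjusted
  model supports both D-dimer scales, since the scale used by the original
  adjusted analysis is ambiguous.

## Problem sizes used by the checks

The test-suite runs reduced-size versions of the statistical properties
(e.g. null-association recovery over 30 cohorts of n = 100; confounding-bias
reduction over 6 cohorts of n = 150; calibration-in-the-large over ~400
subjects at 60 Monte-Carlo draws each), while `scripts/acceptance.R` runs
the full calibrated designs: the 200,000-subject constant-hazard benchmark,
20 joint-model fits at n = 500, 20 mixed-model fits at n = 200 on each
scale, and 50 Weibull fits at n = 1000. Monte-Carlo error bounds in the
tests are derived from the corresponding binomial or replicate-level
standard errors.

## Known limitations

* Predictions ignore competing death, so absolute risks are mildly
  overestimated where mortality is high; a competing-risk joint model is out
  of scope.
* The quadrature centers ignore the survival factor; with very strong
  associations and very sparse histories the 9-node default could in
  principle lose accuracy (the node-refinement check guards the regimes
  exercised here).
* The first-derivative association applies to the linear-trend slope; no
  nonlinear time bases are offered beyond the polynomial AIC sensitivity
  check.
* Estimation at few events (< 5) triggers a warning but is not prevented.
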