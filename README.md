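# jointtraj

Dynamic assessment of venous thromboembolism (VTE) risk in cancer patients
from longitudinal D-dimer measurements.

Cancer induces a hypercoagulable state, and the fibrin-degradation product
D-dimer is one of the strongest biomarkers of cancer-associated VTE risk.
Because both the disease and the coagulation system evolve over a patient's
treatment course, a biomarker *trajectory* observed over repeated monthly
visits may carry prognostic information that a single baseline measurement
cannot — but survivors' trajectories are informatively censored (patients
with rising D-dimer preferentially thrombose or die), so naive longitudinal
summaries are biased. `jointtraj` is for biostatisticians and clinical
researchers who want to analyse this situation with a **joint model of
longitudinal and time-to-event data** and to issue **individualized,
dynamically updated risk predictions** from it.

## The model

A random-intercept-and-slope trajectory on the log2 scale (one unit = one
doubling of D-dimer),

```
y_ij = m_i(t_ij) + e_ij,    m_i(t) = (b0 + b0i) + (b1 + b1i) t + x_i' gL,
(b0i, b1i) ~ N(0, D),       e_ij ~ N(0, sigma^2),
```

coupled to a Weibull proportional-hazards event submodel through the
current value of the latent trajectory,

```
h_i(t) = lambda p t^(p-1) exp{ w_i' gS + alpha m_i(t) + alpha_d m_i'(t) },
```

with `exp(alpha)` the hazard ratio per doubling of D-dimer at any time of
follow-up. The shared random effects are integrated out by adaptive
Gauss-Hermite quadrature (analytic per-subject re-centering each likelihood
evaluation; Rcpp kernel); maximum likelihood throughout. Around this core
the package provides Aalen-Johansen competing-risk cumulative incidence,
1−Kaplan-Meier, baseline Weibull PH regression (per-unit / per-5 /
per-doubling covariates), per-group descriptive trajectory slopes,
conditional risk prediction beyond a landmark time, and a calibrated
synthetic-cohort generator, all tibble-in/tibble-out with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(jointtraj)

# a 167-patient synthetic cohort with study-like structure
coh <- simulate_cohort(paper_like_params(seed = 1))
ds  <- build_dataset(coh$visits, coh$patients)   # cap 40 ug/mL, LOD floor
ds$exclusions
#> # A tibble: 1 × 2
#>   patient_id reason
#>   <chr>      <chr>
#> 1 P0002      D-dimer > 40 ug/mL

# descriptive per-group slopes (ug/mL per 30-day month)
fit_ug <- fit_lmm(ds, scale = "original_ugml", group_by_event = TRUE)
group_slopes(fit_ug)
#> # A tibble: 2 × 6
#>   group  slope_per_unit std_error conf_low conf_high  p_value
#> 1 no_VTE         0.0472    0.0406  -0.0325     0.127 2.45e- 1
#> 2 VTE            0.970     0.140    0.696      1.24  4.26e-12

# competing-risk cumulative incidence at day 250
aj <- aalen_johansen(ds$patients)
incidence_at(aj$VTE, 250)
#> [1] 0.09036145
km <- kaplan_meier(ds$patients)
incidence_at(km, 250)        # always >= the Aalen-Johansen estimate
#> [1] 0.107987

# the joint model: hazard ratio per doubling of the latent trajectory
fit <- fit_joint_model(ds, jm_spec(scale = "log2"))
fit
#> <joint_model_fit> scale=log2, 166 subjects, 15 VTE events
#>   logLik -1215.666, AIC 2449.332
#>   Weibull baseline: shape 1.222, scale 2.986e-05
#>   alpha_current = 1.036 (SE 0.207), HR = 2.817

# dynamic prediction for one patient from day 120
h  <- patient_history(ds, "P0003", up_to_days = 120)
pr <- predict_risk(fit, h, landmark_s = 120,
                   horizons = seq(120, 300, 30), seed = 1)
autoplot(pr)
```

The per-group slope table shows the signature pattern: flat trajectories in
patients who never develop VTE, rising trajectories (here ~1 µg/mL/month
under the generating parameters) in those who do. The joint-model `HR`
(here 2.82 with 15 events; simulation truth `exp(1.0225) = 2.78`) is the
hazard ratio per doubling; at n = 167 its sampling spread across seeds is
substantial, which is exactly what the calibrated acceptance experiments
quantify. The prediction plot shows the conditional VTE-risk curve beyond
the landmark with its Monte-Carlo band.

A full pipeline (simulate → preprocess → mixed models → incidence → joint
models → predictions, with provenance-stamped CSV/JSON outputs) is available
as `run_pipeline(config)`, and a thin CLI over the same functions ships in
`inst/cli/jointtraj.R`.

## Package layout

- `R/params.R`, `R/simulate.R` — cohort parameters, calibration solvers, and
  the generators (trajectory-linked cohorts, constant-hazard competing-risk
  benchmarks, plain LMM trajectories, baseline-Weibull cohorts)
- `R/preprocess.R` — validation, per-patient exclusion, LOD flooring, log2
  transform
- `R/lmm.R` — ML mixed model, per-group slopes, contrasts, %/month
- `R/incidence.R`, `R/weibull.R` — KM / Aalen-Johansen, Weibull PH ML
- `R/joint_model.R`, `src/joint_loglik.cpp` — the joint likelihood, fitting,
  AIC comparison, covariate-adjusted and stratum-specific variants
- `R/dynamic_prediction.R` — empirical-Bayes modes, conditional risk curves
- `R/pipeline.R` — the reproducible end-to-end pipeline
- `vignettes/dynamic-vte-risk.Rmd` — model, numerics, calibration choices,
  and what the synthetic experiments do and do not demonstrate
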