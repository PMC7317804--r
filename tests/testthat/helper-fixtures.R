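# shared fixtures and small oracles, all generated in code

# cohort parameters matching the alpha-recovery simulation design:
# log2-scale trajectories, Weibull(1) baseline calibrated to ~12% 250-day
# incidence, association 1.0225 per doubling
recovery_params <- function(seed, n = 500, alpha = 1.0225,
                            intercept_sd = 1.2, slope_sd = 0.01,
                            sigma_eps = 0.4, death_hazard = 0) {
  D <- diag(c(intercept_sd^2, slope_sd^2))
  lam <- calibrate_weibull_scale(0.12, 250, alpha, log2(0.97), 0, D,
                                 shape = 1, death_hazard = death_hazard)
  cohort_params(
    n_subjects = n, visit_interval_days = 30, visit_jitter_sd_days = 0,
    max_followup_days = 250, max_visits = 9, beta0 = log2(0.97), beta1 = 0,
    D = D, sigma_eps = sigma_eps, weibull_shape = 1, weibull_scale = lam,
    alpha = alpha, death_hazard = death_hazard, seed = seed
  )
}

# dataset built from a simulated cohort, without the >40 ug/mL exclusion so
# that generating parameters stay exactly those of the simulation
build_sim_dataset <- function(cohort, ddimer_cap = Inf) {
  build_dataset(cohort$visits, cohort$patients, ddimer_cap = ddimer_cap)
}

quiet_fit_lmm <- function(...) suppressWarnings(fit_lmm(...))

# marginal log-likelihood oracle for the random-intercept-and-slope LMM:
# direct evaluation of each subject's stacked multivariate normal density
# with covariance Z D Z' + sigma^2 I
lmm_loglik_oracle <- function(df, beta_fun, D, sigma2) {
  # beta_fun(row) -> fitted fixed-effect mean for each observation
  sum(vapply(split(df, df$patient_id), function(d) {
    r <- d$y - beta_fun(d)
    Z <- cbind(1, d$time)
    V <- Z %*% D %*% t(Z) + diag(sigma2, nrow(d))
    -0.5 * (nrow(d) * log(2 * pi) +
              as.numeric(determinant(V)$modulus) +
              drop(t(r) %*% solve(V) %*% r))
  }, numeric(1)))
}

# closed-form VTE cumulative incidence under two constant cause-specific
# hazards: F1(t) = l1/(l1+l2) (1 - exp(-(l1+l2) t))
cif_constant_hazards <- function(t, l1, l2) {
  l1 / (l1 + l2) * (1 - exp(-(l1 + l2) * t))
}

# tiny hand-computable patient tables
hand_cohort_km <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:4),
    event_time_days = c(1, 2, 3, 4),
    event_type = factor(c("VTE", "censored", "VTE", "censored"),
                        levels = c("censored", "VTE", "death"))
  )
}

hand_cohort_aj <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:4),
    event_time_days = c(1, 2, 3, 4),
    event_type = factor(c("VTE", "death", "censored", "VTE"),
                        levels = c("censored", "VTE", "death"))
  )
}
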