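noise_free_groups <- function(slope_a = 0.02, slope_b = 0.02) {
  # two groups of deterministic lines with distinct intercepts per subject
  grid <- tidyr::expand_grid(i = 1:12, time_days = seq(0, 180, 30))
  df <- dplyr::mutate(
    grid,
    patient_id = sprintf("P%02d", i),
    event_type = ifelse(i <= 6, "VTE", "censored"),
    slope = ifelse(i <= 6, slope_a, slope_b),
    value = 1 + 0.1 * i + slope * time_days
  )
  df$event_type <- factor(df$event_type, levels = c("censored", "VTE", "death"))
  df
}

test_that("noise-free data recover the generating slope exactly", {
  df <- simulate_lmm_trajectories(20, n_visits = 6, intercept_mean = 1,
                                  intercept_sd = 0.5,
                                  slope_mean_per_day = 0.02,
                                  slope_sd_per_day = 0, resid_sd = 0,
                                  seed = 1)
  fit <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "days")
  slope <- fit$fixed_effects$estimate[fit$fixed_effects$term == "time"]
  expect_equal(slope, 0.02, tolerance = 1e-8)
})

test_that("ML fixed effects equal the GLS closed form at the fitted variances", {
  df <- simulate_lmm_trajectories(40, n_visits = 5, intercept_mean = 1,
                                  intercept_sd = 0.8,
                                  slope_mean_per_day = 0.01,
                                  slope_sd_per_day = 0.004, resid_sd = 0.5,
                                  seed = 2)
  fit <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "days")
  # independent matrix oracle: balanced data so V is shared across subjects
  tt <- unique(df$time_days)
  Z <- cbind(1, tt)
  V <- Z %*% fit$D_hat %*% t(Z) + diag(fit$sigma2_hat, length(tt))
  Vinv <- solve(V)
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (d in split(df, df$patient_id)) {
    X <- cbind(1, d$time_days)
    XtVX <- XtVX + t(X) %*% Vinv %*% X
    XtVy <- XtVy + t(X) %*% Vinv %*% d$value
  }
  beta_gls <- drop(solve(XtVX, XtVy))
  expect_equal(unname(fit$fixed_effects$estimate), beta_gls,
               tolerance = 1e-6)
})

test_that("fitted log-likelihood matches the stacked multivariate-normal oracle", {
  df <- simulate_lmm_trajectories(15, n_visits = 5, intercept_sd = 1,
                                  slope_mean_per_day = 0.01,
                                  slope_sd_per_day = 0.005, resid_sd = 0.6,
                                  seed = 3)
  fit <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "days")
  b <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  frame <- fit$frame
  ll_oracle <- lmm_loglik_oracle(
    frame,
    beta_fun = function(d) b["(Intercept)"] + b["time"] * d$time,
    D = fit$D_hat, sigma2 = fit$sigma2_hat
  )
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-6)
  # AIC identity 2k - 2 loglik
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$loglik, tolerance = 1e-10)
})

test_that("slope contrast is zero for identical groups and matches separate fits", {
  df <- noise_free_groups(0.02, 0.02)
  fit <- quiet_fit_lmm(df, scale = "original_ugml", group_by_event = TRUE,
                       time_unit = "days")
  ct <- slope_contrast(fit)
  expect_equal(ct$estimate, 0, tolerance = 1e-8)
  expect_gt(ct$p_value, 0.99)

  df2 <- noise_free_groups(0.05, 0.01)
  fit2 <- quiet_fit_lmm(df2, scale = "original_ugml", group_by_event = TRUE,
                        time_unit = "days")
  ct2 <- slope_contrast(fit2)
  # oracle: two separate single-group fits
  fa <- quiet_fit_lmm(dplyr::filter(df2, event_type == "VTE"),
                      scale = "original_ugml", time_unit = "days")
  fb <- quiet_fit_lmm(dplyr::filter(df2, event_type != "VTE"),
                      scale = "original_ugml", time_unit = "days")
  sa <- fa$fixed_effects$estimate[fa$fixed_effects$term == "time"]
  sb <- fb$fixed_effects$estimate[fb$fixed_effects$term == "time"]
  expect_equal(ct2$estimate, sa - sb, tolerance = 1e-7)
  expect_error(slope_contrast(fa), "group_by_event")
})

test_that("slope-difference CI has near-nominal coverage", {
  truth <- 0.53 / 30  # per day
  hits <- 0
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 60
    grp_vte <- rep(c(TRUE, FALSE), c(20, 40))
    b0 <- rnorm(n, 1.8, 1.0)
    b1 <- rnorm(n, ifelse(grp_vte, truth, 0), 0.003)
    df <- tidyr::expand_grid(i = 1:n, time_days = seq(0, 180, 30)) |>
      dplyr::mutate(
        patient_id = sprintf("P%03d", i),
        event_type = factor(ifelse(grp_vte[i], "VTE", "censored"),
                            levels = c("censored", "VTE", "death")),
        value = b0[i] + b1[i] * time_days + rnorm(dplyr::n(), 0, 0.8)
      )
    fit <- quiet_fit_lmm(df, scale = "original_ugml", group_by_event = TRUE,
                         time_unit = "days")
    ct <- slope_contrast(fit)
    if (ct$conf_low <= truth && truth <= ct$conf_high) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("percent change per month back-transforms log-scale slopes", {
  # zero slope -> 0 %/month
  df <- noise_free_groups(0, 0)
  fit0 <- quiet_fit_lmm(df, scale = "natural_log", group_by_event = TRUE,
                        time_unit = "months", response = "value")
  pc0 <- percent_change_per_month(fit0)
  expect_equal(pc0$pct_per_month, c(0, 0), tolerance = 1e-6)

  # natural-log slope 0.29267/month -> 34.0 %/month
  df2 <- noise_free_groups(0.29267 / 30, 0)
  fit2 <- quiet_fit_lmm(df2, scale = "natural_log", group_by_event = TRUE,
                        time_unit = "months", response = "value")
  pc2 <- percent_change_per_month(fit2)
  expect_equal(pc2$pct_per_month[pc2$group == "VTE"],
               100 * (exp(0.29267) - 1), tolerance = 1e-4)
  expect_equal(100 * (exp(0.29267) - 1), 34.0, tolerance = 0.05)

  fit_ug <- quiet_fit_lmm(df2, scale = "original_ugml", time_unit = "months")
  expect_error(percent_change_per_month(fit_ug), "log-scale")
})

test_that("linear time is preferred by AIC when the truth is linear", {
  df <- simulate_lmm_trajectories(120, n_visits = 7, intercept_sd = 1,
                                  slope_mean_per_day = 0.015,
                                  slope_sd_per_day = 0.005, resid_sd = 0.7,
                                  seed = 8)
  f1 <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "months")
  f3 <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "months",
                      time_degree = 3)
  expect_lte(f1$aic, f3$aic)
})

test_that("slope recovery is unbiased under the study-like design", {
  # truth 0.015667 ug/mL/day = 0.47 per 30-day month
  est <- vapply(1:8, function(r) {
    df <- simulate_lmm_trajectories(
      200, n_visits = 7, visit_interval_days = 30,
      intercept_mean = 1.88, intercept_sd = 1.0,
      slope_mean_per_day = 0.015667, slope_sd_per_day = 0.003,
      resid_sd = 0.8, seed = 300 + r)
    fit <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "months")
    fit$fixed_effects$estimate[fit$fixed_effects$term == "time"]
  }, numeric(1))
  # MC SE of the mean slope: slope SD 0.09/month across subjects
  expect_lt(abs(mean(est) - 0.47), 2 * 0.09 / sqrt(200 * 8) + 0.01)
})
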