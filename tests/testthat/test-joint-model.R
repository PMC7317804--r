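toy_dataset <- function(n = 5, seed = 17, alpha = 0.8) {
  pars <- cohort_params(
    n_subjects = n, beta0 = 0, beta1 = 0.003, D = diag(c(1, 0.005^2)),
    sigma_eps = 0.5, weibull_shape = 1, weibull_scale = 8e-4,
    alpha = alpha, max_visits = 6, max_followup_days = 250, seed = seed)
  coh <- simulate_cohort(pars)
  build_sim_dataset(coh)
}

toy_params <- function(alpha = 0) {
  list(beta = c(0.1, 0.002), D = matrix(c(0.9, 0.001, 0.001, 4e-5), 2),
       sigma = 0.45, lambda = 7e-4, shape = 1.1, alpha = alpha)
}

test_that("with alpha = 0 the joint likelihood separates into LMM + Weibull", {
  ds <- toy_dataset(n = 20, seed = 31)
  pp <- toy_params(alpha = 0)
  ll_joint <- joint_loglikelihood(pp, ds, jm_spec(scale = "log2"))

  mf <- jointtraj:::model_frame(ds, "log2", "days")
  mf$y <- mf$log2_ddimer
  ll_lmm <- lmm_loglik_oracle(
    mf, beta_fun = function(d) pp$beta[1] + pp$beta[2] * d$time_days,
    D = pp$D, sigma2 = pp$sigma^2)
  ll_wb <- jointtraj:::weibull_ph_loglik(
    ds$patients$event_time_days,
    as.integer(ds$patients$event_type == "VTE"),
    pp$lambda, pp$shape)
  expect_equal(ll_joint, ll_lmm + ll_wb, tolerance = 1e-6)
})

test_that("quadrature likelihood matches a Monte-Carlo oracle per subject", {
  ds <- toy_dataset(n = 5, seed = 41)
  spec <- jm_spec(scale = "log2")
  prep <- jointtraj:::jm_prepare(ds, spec)
  pp <- toy_params(alpha = 0.7)
  theta <- jointtraj:::jm_pack(pp, prep)
  ll_quad <- jointtraj:::jm_loglik_subjects(theta, prep)

  set.seed(1)
  M <- 100000
  B <- matrix(rnorm(2 * M), M, 2) %*% chol(pp$D)
  # hazard integrated on the original time scale (trapezoid-free GL rule),
  # independent of the kernel's unit-interval substitution
  gl <- pracma::gaussLegendre(25, -1, 1)
  for (i in seq_len(prep$n)) {
    rows <- prep$obs_start[i] + seq_len(prep$obs_count[i])
    yr <- prep$y[rows] - (pp$beta[1] + pp$beta[2] * prep$tij[rows])
    Ti <- prep$Tobs[i]
    s <- Ti / 2 * (gl$x + 1); w <- Ti / 2 * gl$w
    resid <- outer(B[, 1], rep(1, length(rows))) +
      outer(B[, 2], prep$tij[rows])
    resid <- sweep(resid, 2, yr, function(m, y) y - m)
    long <- rowSums(dnorm(resid, 0, pp$sigma, log = TRUE))
    mtraj <- pp$beta[1] + pp$beta[2] * outer(rep(1, M), s) +
      B[, 1] + outer(B[, 2], s)
    haz_base <- pp$lambda * pp$shape * s^(pp$shape - 1)
    lsurv <- -drop(exp(pp$alpha * mtraj) %*% (w * haz_base))
    levt <- if (prep$delta[i] == 1) {
      mT <- pp$beta[1] + pp$beta[2] * Ti + B[, 1] + B[, 2] * Ti
      log(pp$lambda * pp$shape) + (pp$shape - 1) * log(Ti) + pp$alpha * mT
    } else 0
    f <- exp(long + lsurv + levt)
    expect_lt(abs(exp(ll_quad[i]) - mean(f)), 3 * sd(f) / sqrt(M))
  }
})

test_that("the likelihood is stable under quadrature refinement", {
  ds <- toy_dataset(n = 8, seed = 43)
  pp <- toy_params(alpha = 0.7)
  ll9 <- joint_loglikelihood(pp, ds, jm_spec(quadrature_nodes = 9))
  ll15 <- joint_loglikelihood(pp, ds, jm_spec(quadrature_nodes = 15))
  expect_lt(abs(ll9 - ll15), 1e-4)
})

test_that("a null association is recovered as null", {
  inside <- vapply(1:30, function(r) {
    pars <- cohort_params(
      n_subjects = 100, beta0 = log2(0.97), D = diag(c(1.2^2, 0.01^2)),
      sigma_eps = 0.4, weibull_shape = 1, weibull_scale = 5.5e-4,
      alpha = 0, max_visits = 9, max_followup_days = 250, seed = 7000 + r)
    coh <- simulate_cohort(pars)
    ds <- build_sim_dataset(coh)
    f <- suppressWarnings(fit_joint_model(ds))
    abs(f$association$estimate[1]) <= 2 * f$association$std_error[1]
  }, logical(1))
  expect_gte(mean(inside), 0.85)
})

test_that("alpha is invariant to the day/month time rescaling", {
  ds <- toy_dataset(n = 120, seed = 47, alpha = 0.9)
  fd <- fit_joint_model(ds, jm_spec(time_unit = "days"))
  fm <- fit_joint_model(ds, jm_spec(time_unit = "months"))
  expect_equal(fd$association$estimate[1], fm$association$estimate[1],
               tolerance = 1e-4)
  # slope and residual sd transform consistently
  expect_equal(fd$beta[["time"]] * 30, fm$beta[["time"]], tolerance = 1e-3)
  expect_equal(fd$sigma2_hat, fm$sigma2_hat, tolerance = 1e-3)
})

test_that("log2- and natural-log-scale fits satisfy alpha_log2 = alpha_ln * ln 2", {
  ds <- toy_dataset(n = 120, seed = 53, alpha = 0.9)
  f2 <- fit_joint_model(ds, jm_spec(scale = "log2"))
  # feeding 2^(ln ddimer) makes the "log2" response the natural log
  vis_ln <- dplyr::mutate(ds$visits, ddimer_ugml = 2^log(.data$ddimer_ugml))
  ds_ln <- build_dataset(vis_ln, ds$patients, ddimer_cap = Inf)
  fln <- fit_joint_model(ds_ln, jm_spec(scale = "log2"))
  expect_equal(f2$association$estimate[1],
               fln$association$estimate[1] * log(2), tolerance = 1e-4)
})

test_that("compare_fits ranks by AIC and guards scale mixing", {
  ds <- toy_dataset(n = 60, seed = 59)
  f1 <- quiet_fit_lmm(ds, scale = "log2")
  expect_equal(compare_fits(list(only = f1))$delta_aic, 0)

  f3 <- quiet_fit_lmm(ds, scale = "log2", time_degree = 3)
  tab <- compare_fits(list(linear = f1, cubic = f3))
  expect_identical(tab$model[1], "linear")

  fu <- quiet_fit_lmm(ds, scale = "original_ugml")
  expect_error(compare_fits(list(a = f1, b = fu)), "scale")
  tab2 <- compare_fits(list(log2 = f1, original = fu),
                       correct_jacobian = TRUE)
  # right-skewed biomarker: the log2 model wins on the common scale
  expect_identical(tab2$model[1], "log2")

  # nested LMMs differing by one parameter: AIC agrees with the LR rule
  df <- simulate_lmm_trajectories(80, seed = 61, intercept_sd = 1,
                                  slope_mean_per_day = 0.01,
                                  slope_sd_per_day = 0.004, resid_sd = 0.5)
  df$z <- rep(rnorm(80), each = 7)
  df$value <- df$value + 0.8 * df$z
  fit0 <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "days")
  fit1 <- quiet_fit_lmm(df, scale = "original_ugml", time_unit = "days",
                        covariates = "z")
  lr <- 2 * (fit1$loglik - fit0$loglik)
  expect_gt(lr, 2)
  tabn <- compare_fits(list(without = fit0, with = fit1))
  expect_identical(tabn$model[1], "with")
})

test_that("adjusting for a null covariate leaves alpha essentially unchanged", {
  pars <- recovery_params(73, n = 150)
  coh <- simulate_cohort(pars)   # khorana_points has no effect in the truth
  ds <- build_sim_dataset(coh)
  f0 <- suppressWarnings(fit_joint_model(ds))
  fa <- suppressWarnings(adjusted_fit(ds, covariates = "khorana_points"))
  expect_lt(abs(fa$association$estimate[1] - f0$association$estimate[1]),
            2 * f0$association$std_error[1])
})

test_that("adjustment reduces confounding bias on average", {
  deltas <- vapply(1:6, function(r) {
    n <- 150
    pars <- cohort_params(
      n_subjects = n, beta0 = 0, D = diag(c(0.8^2, 0.008^2)),
      sigma_eps = 0.4, weibull_shape = 1, weibull_scale = 4e-4,
      alpha = 0.6, gamma_L = c(metastatic = 0.9),
      gamma_S = c(metastatic = 0.8),
      max_visits = 8, max_followup_days = 250, seed = 9000 + r)
    coh <- simulate_cohort(pars)
    ds <- build_sim_dataset(coh)
    f_unadj <- suppressWarnings(fit_joint_model(ds))
    f_adj <- suppressWarnings(adjusted_fit(ds, covariates = "metastatic"))
    abs(f_unadj$association$estimate[1] - 0.6) -
      abs(f_adj$association$estimate[1] - 0.6)
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

test_that("a stratum-specific association can be requested and reported", {
  pars <- recovery_params(79, n = 150)
  coh <- simulate_cohort(pars)
  ds <- build_sim_dataset(coh)
  f <- suppressWarnings(
    fit_joint_model(ds, jm_spec(association_by = "metastatic")))
  expect_identical(nrow(f$association), 2L)
  expect_true(all(is.finite(f$association$estimate)))
  td <- tidy(f)
  expect_true("alpha_x_metastatic" %in% td$term)
})

test_that("the first-derivative association is estimable and near-null when absent", {
  ds <- toy_dataset(n = 150, seed = 83, alpha = 0.8)
  f <- suppressWarnings(fit_joint_model(
    ds, jm_spec(association = c("current_value", "first_derivative"))))
  ad <- dplyr::filter(f$association, term == "alpha_derivative")
  expect_identical(nrow(ad), 1L)
  expect_true(is.finite(ad$estimate))
})
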