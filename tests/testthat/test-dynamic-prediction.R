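# a fit object with known parameters (no estimation noise, zero vcov)
truth_fit <- function(alpha = 1.0225, lambda = 5e-4, shape = 1,
                      D = diag(c(1.2^2, 0.01^2)), sigma = 0.4,
                      beta = c(log2(0.97), 0)) {
  manual_joint_fit(beta = beta, D = D, sigma = sigma, lambda = lambda,
                   shape = shape, alpha = alpha, spec = jm_spec())
}

flat_history <- function(level = 2, times = c(0, 30, 60, 90)) {
  list(visits = tibble::tibble(time_days = times,
                               ddimer_ugml = rep(level, length(times))),
       covariates = tibble::tibble(patient_id = "H1"))
}

test_that("risk at the landmark itself is exactly zero and bands are sane", {
  fit <- truth_fit()
  pr <- predict_risk(fit, flat_history(), landmark_s = 90,
                     horizons = c(90, 180, 270), n_mc_draws = 100, seed = 1)
  expect_equal(pr$risk[pr$horizon_days == 90], 0)
  expect_true(all(pr$risk >= 0 & pr$risk <= 1))
  expect_true(all(pr$conf_low <= pr$risk & pr$risk <= pr$conf_high))
  expect_error(predict_risk(fit, flat_history(), 90, horizons = 30), "landmark")
  expect_error(predict_risk(fit, flat_history(), 60, horizons = 120),
               "last visit")
})

test_that("risk is nondecreasing in the horizon", {
  fit <- truth_fit()
  hor <- seq(90, 450, by = 30)
  pr <- predict_risk(fit, flat_history(), 90, hor, n_mc_draws = 200, seed = 2)
  expect_true(all(diff(pr$risk) >= 0))
})

test_that("with alpha = 0 the prediction equals the conditional Weibull risk", {
  lam <- 8e-4; p <- 1.3
  fit <- truth_fit(alpha = 0, lambda = lam, shape = p)
  s <- 90; u <- c(180, 270)
  pr <- predict_risk(fit, flat_history(), s, u, n_mc_draws = 50, seed = 3,
                     include_parameter_uncertainty = FALSE)
  closed <- 1 - exp(-lam * (u^p - s^p))
  expect_equal(pr$risk[match(u, pr$horizon_days)], closed, tolerance = 1e-8)
})

test_that("a rising trajectory yields higher risk than a flat one, and a
           doubled history raises risk when alpha > 0", {
  fit <- truth_fit()
  flat <- flat_history(level = 2)
  rising <- list(
    visits = tibble::tibble(time_days = c(0, 30, 60, 90),
                            ddimer_ugml = c(0.5, 1, 2.5, 6)),
    covariates = tibble::tibble(patient_id = "H2"))
  pf <- predict_risk(fit, flat, 90, 270, n_mc_draws = 400, seed = 4)
  pr <- predict_risk(fit, rising, 90, 270, n_mc_draws = 400, seed = 4)
  expect_gt(pr$risk, pf$risk)

  doubled <- flat_history(level = 4)
  pd <- predict_risk(fit, doubled, 90, 270, n_mc_draws = 400, seed = 4)
  expect_gt(pd$risk, pf$risk)
})

test_that("empirical-Bayes mode matches a grid-search oracle", {
  fit <- truth_fit()
  h <- list(
    visits = tibble::tibble(time_days = c(0, 30, 60),
                            ddimer_ugml = c(1.2, 1.8, 3.1)),
    covariates = tibble::tibble(patient_id = "G1"))
  eb <- empirical_bayes_modes(fit, h, landmark_s = 60)
  # oracle: dense lattice over b
  np <- jointtraj:::jm_natural(fit$theta, fit)
  lp <- jointtraj:::history_lp(np, fit, h)
  y <- log2(h$visits$ddimer_ugml); tt <- h$visits$time_days
  Dinv <- solve(np$D)
  obj <- function(b1, b2) {
    res <- y - (lp$a_fix + lp$c_slope * tt) - b1 - b2 * tt
    -0.5 * sum(res^2) / np$sigma2 -
      0.5 * (b1^2 * Dinv[1, 1] + 2 * b1 * b2 * Dinv[1, 2] +
               b2^2 * Dinv[2, 2]) -
      jointtraj:::cumhaz_increment(np, lp, c(b1, b2), 0, 60)
  }
  g1 <- seq(eb$mode[1] - 1, eb$mode[1] + 1, length.out = 201)
  g2 <- seq(eb$mode[2] - 0.03, eb$mode[2] + 0.03, length.out = 201)
  vals <- outer(g1, g2, Vectorize(obj))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(g1[best[1]] - eb$mode[1]), (g1[2] - g1[1]) * 1.5)
  expect_lt(abs(g2[best[2]] - eb$mode[2]), (g2[2] - g2[1]) * 1.5)
})

test_that("noise-free observations pin down the true random effect", {
  fit <- truth_fit(sigma = 1e-4)
  b_true <- c(0.9, 0.012)
  tt <- c(0, 30, 60, 90)
  y <- 2^(log2(0.97) + b_true[1] + b_true[2] * tt)
  h <- list(visits = tibble::tibble(time_days = tt, ddimer_ugml = y),
            covariates = tibble::tibble(patient_id = "N1"))
  eb <- empirical_bayes_modes(fit, h, 90, include_survival = FALSE)
  expect_lt(max(abs(eb$mode - b_true)), 0.01)
})

test_that("the survival-to-landmark term pulls the trajectory mode down", {
  fit <- truth_fit(alpha = 1.0225)
  h <- flat_history(level = 3, times = c(0, 60, 120, 180))
  full <- empirical_bayes_modes(fit, h, landmark_s = 240)
  lmm_only <- empirical_bayes_modes(fit, h, landmark_s = 240,
                                    include_survival = FALSE)
  expect_lt(full$mode[2], lmm_only$mode[2])
})

test_that("longer histories shrink the prediction band on average", {
  fit <- truth_fit()
  set.seed(5)
  widths <- vapply(c(2, 6), function(k) {
    mean(vapply(1:12, function(r) {
      b <- c(rnorm(1, 0, 1.2), rnorm(1, 0, 0.01))
      tt <- seq(0, 150, length.out = k)
      y <- 2^(log2(0.97) + b[1] + b[2] * tt + rnorm(k, 0, 0.4))
      h <- list(visits = tibble::tibble(time_days = tt, ddimer_ugml = y),
                covariates = tibble::tibble(patient_id = "W"))
      pr <- predict_risk(fit, h, 150, 330, n_mc_draws = 300,
                         seed = 50 + r)
      pr$conf_high - pr$conf_low
    }, numeric(1)))
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("the Metropolis sampler agrees with the normal approximation", {
  fit <- truth_fit()
  h <- flat_history()
  p_norm <- predict_risk(fit, h, 90, 270, n_mc_draws = 2000, seed = 6,
                         b_sampler = "normal")
  p_mh <- predict_risk(fit, h, 90, 270, n_mc_draws = 2000, seed = 7,
                       b_sampler = "metropolis")
  expect_lt(abs(p_norm$risk - p_mh$risk), 0.02)
})

test_that("predictions are calibrated in the large under the truth", {
  # simulate subjects, predict 180-day risk from day 60 for those still at
  # risk, and compare the mean prediction with the empirical event fraction
  pars <- recovery_params(101, n = 1000, death_hazard = 0)
  pars$max_followup_days <- 400
  pars$weibull_scale <- calibrate_weibull_scale(
    0.12, 250, 1.0225, log2(0.97), 0, diag(c(1.2^2, 0.01^2)), shape = 1)
  coh <- simulate_cohort(pars)
  fit <- truth_fit(alpha = pars$alpha, lambda = pars$weibull_scale,
                   shape = 1, D = pars$D, sigma = pars$sigma_eps,
                   beta = c(pars$beta0, pars$beta1))
  s <- 60; u <- 240
  at_risk <- dplyr::filter(coh$patients, event_time_days > s)
  preds <- vapply(seq_len(nrow(at_risk)), function(i) {
    id <- at_risk$patient_id[i]
    vis <- dplyr::filter(coh$visits, patient_id == id, time_days <= s)
    if (nrow(vis) == 0) return(NA_real_)
    h <- list(visits = vis[c("time_days", "ddimer_ugml")],
              covariates = at_risk[i, ])
    predict_risk(fit, h, s, u, n_mc_draws = 60, seed = 200 + i)$risk
  }, numeric(1))
  ok <- !is.na(preds)
  emp <- mean(at_risk$event_type[ok] == "VTE" &
                at_risk$event_time_days[ok] <= u)
  mc_se <- sqrt(emp * (1 - emp) / sum(ok))
  expect_lt(abs(mean(preds[ok]) - emp), 2 * mc_se + 0.01)
})
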