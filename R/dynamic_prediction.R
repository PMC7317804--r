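#' Extract one patient's history from an analysis dataset
#'
#' Convenience constructor of the `history` argument of
#' [empirical_bayes_modes()] / [predict_risk()]: the patient's visits up to
#' (and including) `up_to_days`, plus their baseline covariate row.
#'
#' @param data An `analysis_dataset`.
#' @param patient_id Patient identifier.
#' @param up_to_days Keep only visits at or before this time (default all).
#' @return List with `visits` (tibble: `time_days`, `ddimer_ugml`) and
#'   `covariates` (one-row tibble).
#' @export
patient_history <- function(data, patient_id, up_to_days = Inf) {
  stopifnot(inherits(data, "analysis_dataset"))
  if (!patient_id %in% data$patients$patient_id) {
    abort(paste("Unknown patient:", patient_id))
  }
  list(
    visits = data$visits |>
      dplyr::filter(.data$patient_id == !!patient_id,
                    .data$time_days <= up_to_days) |>
      dplyr::select("time_days", "ddimer_ugml"),
    covariates = dplyr::filter(data$patients,
                               .data$patient_id == !!patient_id)
  )
}

# subject-level quantities for a history under natural parameters np
history_lp <- function(np, fit, history) {
  spec <- fit$spec
  lcov <- spec$longitudinal_covariates
  scov <- spec$survival_covariates
  covs <- history$covariates
  getv <- function(cols) {
    if (is.null(cols)) return(numeric(0))
    if (!all(cols %in% names(covs))) {
      abort(paste("History lacks covariate(s):",
                  paste(setdiff(cols, names(covs)), collapse = ", ")))
    }
    as.numeric(covs[1, cols])
  }
  a_fix <- np$beta[1] +
    (if (length(lcov)) sum(getv(lcov) * np$beta[-(1:2)]) else 0)
  eta <- if (length(scov)) sum(getv(scov) * np$gamma_S) else 0
  z <- if (is.null(spec$association_by)) 0 else
    as.numeric(covs[[spec$association_by]][1])
  list(a_fix = a_fix, c_slope = np$beta[2], eta = eta,
       alpha = np$alpha + np$alpha_int * z, alpha_d = np$alpha_deriv)
}

# cumulative hazard increment on [t0, t1] (model time unit) given b
cumhaz_increment <- function(np, lp, b, t0, t1, gl_nodes = 15) {
  if (t1 <= t0) return(0)
  gl <- pracma::gaussLegendre(gl_nodes, t0, t1)
  amp <- np$lambda * np$shape *
    exp(lp$eta + lp$alpha * (lp$a_fix + b[1]) +
          lp$alpha_d * (lp$c_slope + b[2]))
  slope <- lp$alpha * (lp$c_slope + b[2])
  amp * sum(gl$w * gl$x^(np$shape - 1) * exp(slope * gl$x))
}

#' Empirical-Bayes random-effect mode given a biomarker history
#'
#' Maximises the subject's complete-data log-density over the random effect
#' \eqn{b = (b_0, b_1)}: the longitudinal Gaussian terms for the observed
#' visits, the probability of remaining event-free to the landmark time
#' (omitted with `include_survival = FALSE`), and the \eqn{N(0, D)} prior.
#'
#' @param fit A `joint_model_fit`.
#' @param history List with `visits` (`time_days`, `ddimer_ugml`) and
#'   `covariates` (one-row tibble); see [patient_history()].
#' @param landmark_s Landmark time in days (the subject is known event-free
#'   up to here).
#' @param include_survival Include the survival-to-landmark term (the full
#'   conditional mode) or only the longitudinal terms and prior.
#' @return List with `mode` (length-2), `curvature` (2x2 negative Hessian of
#'   the log-density at the mode).
#' @export
empirical_bayes_modes <- function(fit, history, landmark_s,
                                  include_survival = TRUE) {
  stopifnot(inherits(fit, "joint_model_fit"))
  unit <- if (fit$time_unit == "months") 30 else 1
  s <- landmark_s / unit
  np <- jm_natural(fit$theta, fit)
  lp <- history_lp(np, fit, history)
  visits <- history$visits
  if (nrow(visits) == 0) {
    warn("No visits in history; returning the prior mode (0, 0)")
    return(list(mode = c(0, 0), curvature = solve(np$D)))
  }
  tt <- visits$time_days / unit
  y <- switch(fit$scale,
              log2 = log2(pmax(visits$ddimer_ugml, 1e-6)),
              original_ugml = visits$ddimer_ugml)
  r <- y - (lp$a_fix + lp$c_slope * tt)
  Dinv <- solve(np$D)
  negpost <- function(b) {
    res <- r - b[1] - b[2] * tt
    ll <- -0.5 * sum(res^2) / np$sigma2 -
      0.5 * drop(t(b) %*% Dinv %*% b)
    if (include_survival && s > 0) {
      ll <- ll - cumhaz_increment(np, lp, b, 0, s)
    }
    -ll
  }
  opt <- optim(c(0, 0), negpost, method = "BFGS", hessian = TRUE,
               control = list(maxit = 200, reltol = 1e-12))
  list(mode = opt$par, curvature = opt$hessian)
}

#' Dynamic individualized VTE-risk prediction
#'
#' Conditional risk of VTE over future horizons given survival to the
#' landmark time and the observed biomarker history:
#' \deqn{\pi(u \mid s) = 1 - E\left[\frac{S_i(u \mid b, \theta)}
#'   {S_i(s \mid b, \theta)}\right],}
#' with the expectation taken by Monte Carlo over draws of \eqn{\theta} from
#' its asymptotic normal distribution and of \eqn{b} from its conditional
#' density given the history and survival to \eqn{s} (normal approximation
#' at the empirical-Bayes mode by default; a random-walk Metropolis sampler
#' of the exact conditional is available). The pointwise band is taken from
#' Monte Carlo percentiles. Competing death is ignored, so predicted risks
#' are mildly conservative (upward) in its presence.
#'
#' @inheritParams empirical_bayes_modes
#' @param landmark_s Landmark time in days; must be at or after the last
#'   visit in the history.
#' @param horizons Numeric vector of prediction times in days, each `>=
#'   landmark_s`.
#' @param n_mc_draws Monte Carlo draws.
#' @param seed Integer seed or `NULL`.
#' @param include_parameter_uncertainty Draw `theta` from its asymptotic
#'   normal (`FALSE` fixes it at the estimate).
#' @param b_sampler `"normal"` (mode + curvature approximation) or
#'   `"metropolis"` (exact conditional via random-walk MH).
#' @param force Allow prediction from a non-converged fit.
#' @return A `dynamic_prediction`: tibble (`horizon_days`, `risk`,
#'   `conf_low`, `conf_high`) with landmark/draw metadata attributes.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(paper_like_params(seed = 7))
#' ds <- build_dataset(coh$visits, coh$patients)
#' fit <- fit_joint_model(ds, jm_spec(scale = "log2"))
#' h <- patient_history(ds, ds$patients$patient_id[1], up_to_days = 120)
#' predict_risk(fit, h, landmark_s = 120, horizons = c(120, 180, 300),
#'              seed = 1)
#' }
#' @export
predict_risk <- function(fit, history, landmark_s, horizons,
                         n_mc_draws = 500, seed = NULL,
                         include_parameter_uncertainty = TRUE,
                         b_sampler = c("normal", "metropolis"),
                         force = FALSE) {
  stopifnot(inherits(fit, "joint_model_fit"))
  b_sampler <- match.arg(b_sampler)
  if (!fit$converged && !force) {
    abort("Refusing to predict from a non-converged fit (use force = TRUE)")
  }
  if (any(horizons < landmark_s)) {
    abort("All horizons must be at or after the landmark time")
  }
  if (nrow(history$visits) > 0 &&
      landmark_s < max(history$visits$time_days)) {
    abort("Landmark must be at or after the last visit in the history")
  }
  if (!is.null(seed)) set.seed(seed)
  unit <- if (fit$time_unit == "months") 30 else 1
  s <- landmark_s / unit
  u <- sort(unique(horizons)) / unit
  M <- n_mc_draws

  eb <- empirical_bayes_modes(fit, history, landmark_s)
  Sb <- tryCatch(solve(eb$curvature), error = function(e) solve(fit$D_hat))

  # theta draws (transformed scale)
  use_theta_unc <- include_parameter_uncertainty && !anyNA(fit$vcov) &&
    any(fit$vcov != 0)
  TH <- if (use_theta_unc) {
    ch <- tryCatch(chol(fit$vcov), error = function(e) {
      ev <- eigen(fit$vcov, symmetric = TRUE)
      chol(ev$vectors %*% diag(pmax(ev$values, 1e-12)) %*% t(ev$vectors))
    })
    matrix(rep(fit$theta, each = M), M) +
      matrix(rnorm(M * length(fit$theta)), M) %*% ch
  } else {
    matrix(rep(fit$theta, each = M), M)
  }

  # b draws
  B <- if (b_sampler == "normal") {
    matrix(rep(eb$mode, each = M), M) +
      matrix(rnorm(2 * M), M) %*% chol(Sb)
  } else {
    mh_sample_b(fit, history, landmark_s, eb, n_draws = M)
  }

  risk <- matrix(0, M, length(u))
  for (m in seq_len(M)) {
    np_m <- jm_natural(TH[m, ], fit)
    lp_m <- history_lp(np_m, fit, history)
    for (j in seq_along(u)) {
      dH <- cumhaz_increment(np_m, lp_m, B[m, ], s, u[j])
      risk[m, j] <- 1 - exp(-dH)
    }
  }
  point <- colMeans(risk)
  if (M >= 2) {
    qs <- apply(risk, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    lo <- pmin(qs[1, ], point); hi <- pmax(qs[2, ], point)
  } else {
    lo <- hi <- point
  }
  out <- tibble::tibble(
    horizon_days = u * unit, risk = point, conf_low = lo, conf_high = hi
  )
  structure(out, class = c("dynamic_prediction", class(out)),
            landmark_days = landmark_s, n_mc_draws = M,
            patient_id = history$covariates$patient_id[1] %||% NA_character_)
}

# random-walk Metropolis on the exact conditional density of b given the
# history and survival to the landmark
mh_sample_b <- function(fit, history, landmark_s, eb, n_draws,
                        burnin = 200, scale = 1.6) {
  unit <- if (fit$time_unit == "months") 30 else 1
  s <- landmark_s / unit
  np <- jm_natural(fit$theta, fit)
  lp <- history_lp(np, fit, history)
  visits <- history$visits
  tt <- visits$time_days / unit
  y <- switch(fit$scale,
              log2 = log2(pmax(visits$ddimer_ugml, 1e-6)),
              original_ugml = visits$ddimer_ugml)
  r <- y - (lp$a_fix + lp$c_slope * tt)
  Dinv <- solve(np$D)
  logpost <- function(b) {
    res <- r - b[1] - b[2] * tt
    -0.5 * sum(res^2) / np$sigma2 - 0.5 * drop(t(b) %*% Dinv %*% b) -
      (if (s > 0) cumhaz_increment(np, lp, b, 0, s) else 0)
  }
  prop_chol <- chol(solve(eb$curvature)) * scale
  b <- eb$mode
  lp_cur <- logpost(b)
  out <- matrix(0, n_draws, 2)
  total <- burnin + n_draws
  for (it in seq_len(total)) {
    cand <- b + drop(rnorm(2) %*% prop_chol)
    lp_cand <- logpost(cand)
    if (log(runif(1)) < lp_cand - lp_cur) {
      b <- cand; lp_cur <- lp_cand
    }
    if (it > burnin) out[it - burnin, ] <- b
  }
  out
}

#' @export
print.dynamic_prediction <- function(x, ...) {
  cat(sprintf("<dynamic_prediction> landmark %g d, %d MC draws\n",
              attr(x, "landmark_days"), attr(x, "n_mc_draws")))
  NextMethod()
}

#' Plot a dynamic risk prediction
#'
#' @param object A `dynamic_prediction`.
#' @param ... Unused.
#' @return A ggplot of conditional VTE risk over the horizon grid with its
#'   95% Monte Carlo band.
#' @method autoplot dynamic_prediction
#' @export
autoplot.dynamic_prediction <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$horizon_days, y = .data$risk)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high), alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "landmark_days"),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_continuous(labels = function(b) sprintf("%.0f%%", 100 * b)) +
    ggplot2::labs(x = "Days from baseline",
                  y = "Conditional VTE risk",
                  title = sprintf("Dynamic VTE-risk prediction from day %g",
                                  attr(object, "landmark_days"))) +
    ggplot2::theme_minimal()
}
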