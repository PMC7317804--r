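#' Joint-model specification
#'
#' Describes a joint model of the longitudinal D-dimer trajectory and time
#' to VTE: the biomarker scale, the association structure linking the latent
#' trajectory \eqn{m_i(t)} to the log hazard, covariates for each submodel,
#' and quadrature sizes. The event hazard is
#' \deqn{h_i(t) = \lambda p t^{p-1}
#'   \exp\{w_i'\gamma_S + \alpha\, m_i(t) + \alpha_d\, m_i'(t)\},}
#' with the first-derivative term present only when requested. On the log2
#' scale \eqn{e^\alpha} is the hazard ratio per doubling of D-dimer.
#'
#' @param scale Trajectory scale: `"log2"` or `"original_ugml"`.
#' @param association Non-empty subset of `c("current_value",
#'   "first_derivative")`.
#' @param longitudinal_covariates,survival_covariates Character vectors of
#'   numeric, time-invariant patient columns entering the respective
#'   submodels.
#' @param association_by Optional single binary (0/1) patient column; the
#'   association becomes \eqn{\alpha + \alpha_{int} z_i}, giving a separate
#'   association per stratum.
#' @param quadrature_nodes Gauss-Hermite nodes per random-effect dimension
#'   (odd, >= 3).
#' @param survival_quadrature_nodes Gauss-Legendre nodes for the cumulative
#'   hazard integral (odd, >= 3).
#' @param time_unit `"days"` or `"months"` (30-day) for both submodels.
#' @return A `jm_spec` list.
#' @export
jm_spec <- function(scale = c("log2", "original_ugml"),
                    association = "current_value",
                    longitudinal_covariates = NULL,
                    survival_covariates = NULL,
                    association_by = NULL,
                    quadrature_nodes = 9,
                    survival_quadrature_nodes = 15,
                    time_unit = c("days", "months")) {
  scale <- match.arg(scale)
  time_unit <- match.arg(time_unit)
  stopifnot(length(association) >= 1,
            all(association %in% c("current_value", "first_derivative")))
  for (nn in c(quadrature_nodes, survival_quadrature_nodes)) {
    if (nn < 3 || nn %% 2 == 0) {
      abort("Quadrature node counts must be odd and >= 3")
    }
  }
  structure(list(
    scale = scale, association = association,
    longitudinal_covariates = longitudinal_covariates,
    survival_covariates = survival_covariates,
    association_by = association_by,
    quadrature_nodes = as.integer(quadrature_nodes),
    survival_quadrature_nodes = as.integer(survival_quadrature_nodes),
    time_unit = time_unit
  ), class = "jm_spec")
}

# ---- internal machinery -----------------------------------------------------

# assemble everything the likelihood kernel needs (designs, quadrature rules,
# pseudo-adaptive centers from the standalone LMM fit, initial values)
jm_prepare <- function(data, spec) {
  stopifnot(inherits(data, "analysis_dataset"), inherits(spec, "jm_spec"))
  patients <- data$patients
  n <- nrow(patients)
  unit <- if (spec$time_unit == "months") 30 else 1
  Tobs <- patients$event_time_days / unit
  if (any(Tobs <= 0)) abort("Event/censoring times must be positive")
  delta <- as.integer(patients$event_type == "VTE")

  mf <- model_frame(data, spec$scale, spec$time_unit) |>
    dplyr::arrange(match(.data$patient_id, patients$patient_id),
                   .data$time_days)
  lcov <- spec$longitudinal_covariates
  scov <- spec$survival_covariates
  get_num <- function(cols) {
    if (is.null(cols)) return(matrix(numeric(0), n, 0))
    m <- as.matrix(patients[cols])
    if (!is.numeric(m)) abort("Joint-model covariates must be numeric columns")
    m
  }
  WL <- get_num(lcov)
  WS <- get_num(scov)
  if (ncol(WS) > 1 && qr(cbind(1, WS))$rank < ncol(WS) + 1 ||
      ncol(WL) > 1 && qr(cbind(1, WL))$rank < ncol(WL) + 1) {
    abort("Collinear covariates in the joint-model specification")
  }
  z_assoc <- if (is.null(spec$association_by)) rep(0, n) else {
    z <- patients[[spec$association_by]]
    if (!all(z %in% c(0, 1))) abort("association_by must be a 0/1 column")
    as.numeric(z)
  }

  subj <- match(mf$patient_id, patients$patient_id)
  oc <- tabulate(subj, nbins = n)
  ostart <- c(0L, cumsum(oc))[seq_len(n)]  # 0-based block starts

  # visit-level longitudinal design: intercept, time, covariates
  XL <- cbind(1, mf$time, if (ncol(WL)) WL[subj, , drop = FALSE])
  X0 <- cbind(rep(1, n), 0, if (ncol(WL)) WL)  # subject design at t = 0
  pL <- ncol(XL)

  # initial fits
  lmm <- fit_lmm(data, scale = spec$scale, covariates = lcov,
                 time_unit = spec$time_unit)
  p2 <- patients
  p2$event_time_days <- Tobs
  wb <- fit_weibull_ph(p2, covariates = scov)

  ord <- c("(Intercept)", "time", lcov)

  # per-subject sufficient statistics for the adaptive quadrature centers:
  # the Gaussian posterior of b given only the longitudinal data has
  # precision Z'Z/sigma^2 + D^-1 and is recomputed analytically at every
  # evaluated parameter value (the survival tilt is ignored in the centers)
  St <- Stt <- numeric(n)
  if (length(mf$time)) {
    rs_t <- rowsum(mf$time, subj)
    rs_tt <- rowsum(mf$time^2, subj)
    present <- as.integer(rownames(rs_t))
    St[present] <- rs_t[, 1]
    Stt[present] <- rs_tt[, 1]
  }

  gh <- pracma::gaussHermite(spec$quadrature_nodes)
  grid <- expand.grid(i = seq_along(gh$x), j = seq_along(gh$x))
  tq <- cbind(gh$x[grid$i], gh$x[grid$j])
  logwq <- log(gh$w[grid$i] * gh$w[grid$j]) + tq[, 1]^2 + tq[, 2]^2

  gl <- pracma::gaussLegendre(spec$survival_quadrature_nodes, 0, 1)

  # parameter layout
  has_cur <- "current_value" %in% spec$association
  has_der <- "first_derivative" %in% spec$association
  has_int <- !is.null(spec$association_by)
  nms <- c(ord, "log_sigma", "chol_d1", "chol_d21", "chol_d2",
           "log_lambda", "log_shape",
           if (ncol(WS)) paste0("gamma_", scov),
           if (has_cur) "alpha",
           if (has_der) "alpha_deriv",
           if (has_int) paste0("alpha_x_", spec$association_by))
  idx <- list(
    beta = seq_len(pL),
    log_sigma = pL + 1,
    chol = pL + 2:4,
    log_lambda = pL + 5,
    log_shape = pL + 6,
    gamma_S = if (ncol(WS)) pL + 6 + seq_len(ncol(WS)) else integer(0),
    alpha = if (has_cur) pL + 6 + ncol(WS) + 1 else integer(0),
    alpha_deriv = if (has_der) pL + 6 + ncol(WS) + has_cur + 1 else integer(0),
    alpha_int = if (has_int) pL + 6 + ncol(WS) + has_cur + has_der + 1
                else integer(0)
  )

  list(
    spec = spec, n = n, n_events = sum(delta), unit = unit,
    y = mf$y, tij = mf$time, subj = subj,
    obs_start = as.integer(ostart), obs_count = as.integer(oc),
    XL = XL, X0 = X0, WS = WS, z_assoc = z_assoc,
    Tobs = Tobs, delta = delta,
    St = St, Stt = Stt, tq = tq, logwq = logwq, ugl = gl$x, wgl = gl$w,
    idx = idx, par_names = nms, npar = length(nms),
    lmm = lmm, weibull = wb,
    jacobian_to_original = switch(spec$scale,
      log2 = sum(log(mf$ddimer_ugml * log(2))),
      original_ugml = 0),
    patient_ids = patients$patient_id
  )
}

# transformed parameter vector -> natural parameters
jm_natural <- function(theta, prep) {
  idx <- prep$idx
  L <- matrix(c(exp(theta[idx$chol[1]]), theta[idx$chol[2]],
                0, exp(theta[idx$chol[3]])), 2, 2)
  list(
    beta = theta[idx$beta],
    sigma2 = exp(2 * theta[idx$log_sigma]),
    L = L, D = L %*% t(L),
    lambda = exp(theta[idx$log_lambda]),
    shape = exp(theta[idx$log_shape]),
    gamma_S = theta[idx$gamma_S],
    alpha = if (length(idx$alpha)) theta[idx$alpha] else 0,
    alpha_deriv = if (length(idx$alpha_deriv)) theta[idx$alpha_deriv] else 0,
    alpha_int = if (length(idx$alpha_int)) theta[idx$alpha_int] else 0
  )
}

jm_loglik_subjects <- function(theta, prep) {
  np <- jm_natural(theta, prep)
  resid0 <- prep$y - drop(prep$XL %*% np$beta)
  a_fix <- drop(prep$X0 %*% np$beta)
  eta <- if (ncol(prep$WS)) drop(prep$WS %*% np$gamma_S) else rep(0, prep$n)
  Dinv <- chol2inv(chol(np$D))

  # adaptive centers: analytic posterior of b under the Gaussian submodel
  # at the current parameter value (2x2, fully vectorised)
  n <- prep$n
  Sr <- Srt <- numeric(n)
  if (length(resid0)) {
    rs_r <- rowsum(resid0, prep$subj)
    rs_rt <- rowsum(resid0 * prep$tij, prep$subj)
    present <- as.integer(rownames(rs_r))
    Sr[present] <- rs_r[, 1]
    Srt[present] <- rs_rt[, 1]
  }
  s2 <- np$sigma2
  P11 <- prep$obs_count / s2 + Dinv[1, 1]
  P12 <- prep$St / s2 + Dinv[1, 2]
  P22 <- prep$Stt / s2 + Dinv[2, 2]
  detP <- P11 * P22 - P12^2
  C11 <- P22 / detP; C12 <- -P12 / detP; C22 <- P11 / detP
  g1 <- Sr / s2; g2 <- Srt / s2
  mu <- cbind(C11 * g1 + C12 * g2, C12 * g1 + C22 * g2)
  l11 <- sqrt(C11); l21 <- C12 / l11
  Lmat <- cbind(l11, l21, sqrt(pmax(C22 - l21^2, 1e-300)))

  jm_subject_loglik(
    resid0, prep$tij, prep$obs_start, prep$obs_count, np$sigma2,
    a_fix, np$beta[2], np$alpha, np$alpha_int, prep$z_assoc, np$alpha_deriv,
    eta, log(np$lambda), log(np$shape), prep$Tobs, prep$delta,
    mu, Lmat, prep$tq, prep$logwq, prep$ugl, prep$wgl,
    Dinv, as.numeric(determinant(np$D)$modulus)
  )
}

# ---- public likelihood ------------------------------------------------------

#' Joint log-likelihood at a given parameter set
#'
#' Evaluates the observed-data log-likelihood of the joint model,
#' \deqn{\sum_i \log \int \prod_j N(y_{ij}; m_i(t_{ij}), \sigma^2)\,
#'   h_i(T_i)^{\delta_i} e^{-\int_0^{T_i} h_i(s) ds}\, N(b_i; 0, D)\, db_i,}
#' with the random-effect integral by pseudo-adaptive Gauss-Hermite
#' quadrature and the cumulative-hazard integral by Gauss-Legendre
#' quadrature on \eqn{[0, T_i]}.
#'
#' @param params Named list of natural parameters: `beta` (fixed effects:
#'   intercept, slope per time unit, then longitudinal covariates), `D` (2x2),
#'   `sigma` (residual SD), `lambda`, `shape` (Weibull baseline), optional
#'   `gamma_S`, `alpha`, `alpha_deriv`, `alpha_int`.
#' @param data An `analysis_dataset`.
#' @param spec A [jm_spec()].
#' @return The scalar log-likelihood.
#' @export
joint_loglikelihood <- function(params, data, spec = jm_spec()) {
  prep <- jm_prepare(data, spec)
  theta <- jm_pack(params, prep)
  ll_i <- jm_loglik_subjects(theta, prep)
  if (any(!is.finite(ll_i))) {
    abort(paste("Non-finite likelihood contribution for subject(s):",
                paste(prep$patient_ids[!is.finite(ll_i)], collapse = ", ")))
  }
  sum(ll_i)
}

jm_pack <- function(params, prep) {
  idx <- prep$idx
  theta <- numeric(prep$npar)
  stopifnot(length(params$beta) == length(idx$beta))
  theta[idx$beta] <- params$beta
  theta[idx$log_sigma] <- log(params$sigma)
  L <- t(chol(params$D))
  theta[idx$chol] <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  theta[idx$log_lambda] <- log(params$lambda)
  theta[idx$log_shape] <- log(params$shape)
  if (length(idx$gamma_S)) theta[idx$gamma_S] <- params$gamma_S
  if (length(idx$alpha)) theta[idx$alpha] <- params$alpha %||% 0
  if (length(idx$alpha_deriv)) theta[idx$alpha_deriv] <- params$alpha_deriv %||% 0
  if (length(idx$alpha_int)) theta[idx$alpha_int] <- params$alpha_int %||% 0
  theta
}

# ---- fitting ----------------------------------------------------------------

#' Fit the joint model by maximum likelihood
#'
#' Maximises [joint_loglikelihood()] over all parameters, initialised from
#' the standalone mixed-model and Weibull fits (association terms start at
#' 0). Variance parameters are optimised on log / log-Cholesky transforms;
#' standard errors come from the inverse of a central-finite-difference
#' observed-information matrix.
#'
#' @param data An `analysis_dataset` from [build_dataset()].
#' @param spec A [jm_spec()].
#' @param control Optional list passed to [nlminb()] control.
#' @return A `joint_model_fit` with the longitudinal block
#'   (`beta`, `D_hat`, `sigma2`), Weibull block (`lambda`, `shape`,
#'   `gamma_S`), association estimates with SEs, the full parameter
#'   covariance (transformed scale), `loglik`, `aic` and a `converged` flag.
#'   On optimizer failure the partial fit is returned with
#'   `converged = FALSE` and the optimizer message attached.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(paper_like_params(seed = 7))
#' ds <- build_dataset(coh$visits, coh$patients)
#' fit <- fit_joint_model(ds, jm_spec(scale = "log2"))
#' tidy(fit)
#' }
#' @export
fit_joint_model <- function(data, spec = jm_spec(), control = list()) {
  prep <- jm_prepare(data, spec)
  if (prep$n_events < 5) {
    warn(sprintf("Only %d events; joint-model estimates will be unstable",
                 prep$n_events))
  }
  idx <- prep$idx

  start <- numeric(prep$npar)
  lmm <- prep$lmm
  beta_lmm <- setNames(lmm$fixed_effects$estimate, lmm$fixed_effects$term)
  start[idx$beta] <- unname(
    beta_lmm[c("(Intercept)", "time", spec$longitudinal_covariates)])
  start[idx$log_sigma] <- 0.5 * log(lmm$sigma2_hat)
  Dl <- lmm$D_hat
  ev <- eigen(Dl, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) Dl <- Dl + diag(c(1e-4, 1e-6))
  Ll <- t(chol(Dl))
  start[idx$chol] <- c(log(Ll[1, 1]), Ll[2, 1], log(Ll[2, 2]))
  start[idx$log_lambda] <- log(prep$weibull$scale)
  start[idx$log_shape] <- log(prep$weibull$shape)
  if (length(idx$gamma_S)) {
    start[idx$gamma_S] <- prep$weibull$coefficients$estimate
  }

  negll <- function(th) {
    v <- -sum(jm_loglik_subjects(th, prep))
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- modifyList(list(iter.max = 500, eval.max = 2000, rel.tol = 1e-9),
                     control)
  opt <- nlminb(start, negll, control = ctrl)
  # judge convergence by the score, not only the optimizer's return code
  # ("false convergence" is routinely reported at genuine optima)
  converged <- opt$convergence == 0 ||
    max(abs(fd_gradient(negll, opt$par))) < 1e-4 * (1 + abs(opt$objective))
  if (!converged) {
    warn(paste("Joint model did not converge:", opt$message))
  }
  theta <- opt$par
  ll <- -opt$objective

  H <- fd_hessian(negll, theta)
  vcov_t <- tryCatch(solve(H), error = function(e) {
    warn("Observed information is singular; standard errors unavailable")
    matrix(NA_real_, prep$npar, prep$npar)
  })
  if (!anyNA(vcov_t) && any(diag(vcov_t) < 0)) {
    warn("Observed information is not positive-definite at the optimum")
  }
  dimnames(vcov_t) <- list(prep$par_names, prep$par_names)
  names(theta) <- prep$par_names
  np <- jm_natural(theta, prep)

  assoc <- tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric())
  se_of <- function(j) if (anyNA(vcov_t)) NA_real_ else sqrt(max(vcov_t[j, j], 0))
  if (length(idx$alpha)) {
    assoc <- dplyr::add_row(assoc, term = "alpha_current",
                            estimate = np$alpha, std_error = se_of(idx$alpha))
  }
  if (length(idx$alpha_deriv)) {
    assoc <- dplyr::add_row(assoc, term = "alpha_derivative",
                            estimate = np$alpha_deriv,
                            std_error = se_of(idx$alpha_deriv))
  }
  if (length(idx$alpha_int)) {
    assoc <- dplyr::add_row(assoc, term = paste0("alpha_x_", spec$association_by),
                            estimate = np$alpha_int,
                            std_error = se_of(idx$alpha_int))
  }

  structure(list(
    beta = setNames(np$beta, prep$par_names[idx$beta]),
    D_hat = np$D, sigma2_hat = np$sigma2,
    lambda = np$lambda, shape = np$shape,
    gamma_S = setNames(np$gamma_S, spec$survival_covariates),
    association = assoc,
    theta = theta, vcov = vcov_t, idx = idx,
    loglik = ll, aic = 2 * prep$npar - 2 * ll, k = prep$npar,
    converged = converged, optim_message = opt$message,
    n_subjects = prep$n, n_events = prep$n_events, n_obs = length(prep$y),
    spec = spec, scale = spec$scale, time_unit = spec$time_unit,
    jacobian_to_original = prep$jacobian_to_original
  ), class = "joint_model_fit")
}

#' Joint model with covariate adjustment in both submodels
#'
#' Refits the joint model with the given baseline covariates entering both
#' the longitudinal and the survival submodel (e.g. Khorana score), and
#' optionally a stratum-specific association via `association_by`
#' (e.g. metastatic disease). The association parameter is reported
#' alongside the covariate hazard ratios.
#'
#' @inheritParams fit_joint_model
#' @param covariates Character vector of numeric patient columns entering
#'   both submodels.
#' @param association_by Optional 0/1 patient column for a per-stratum
#'   association.
#' @return A `joint_model_fit`.
#' @export
adjusted_fit <- function(data, covariates, spec = jm_spec(),
                         association_by = NULL, control = list()) {
  spec$longitudinal_covariates <- union(spec$longitudinal_covariates, covariates)
  spec$survival_covariates <- union(spec$survival_covariates, covariates)
  spec$association_by <- association_by %||% spec$association_by
  fit_joint_model(data, spec, control = control)
}

#' Rank fitted models by AIC
#'
#' @param fits Named list of `joint_model_fit` and/or `longitudinal_fit`
#'   objects fitted to the same data.
#' @param correct_jacobian Fits on different outcome scales cannot be ranked
#'   by raw AIC; with `TRUE`, the change-of-variable term
#'   \eqn{2\sum_i \log |d y'_{i}/d y_i|} is added so all AICs refer to the
#'   original µg/mL scale. Mixed scales without this flag are an error.
#' @return Tibble `(model, scale, k, loglik, aic, delta_aic)` sorted by AIC.
#' @export
compare_fits <- function(fits, correct_jacobian = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1)
  labels <- names(fits) %||% paste0("model_", seq_along(fits))
  labels[labels == ""] <- paste0("model_", which(labels == ""))
  rows <- purrr::map2_dfr(fits, labels, function(f, lab) {
    stopifnot(inherits(f, c("joint_model_fit", "longitudinal_fit")))
    k <- if (inherits(f, "joint_model_fit")) f$k else f$df
    tibble::tibble(model = lab, scale = f$scale, k = k, loglik = f$loglik,
                   aic = f$aic,
                   jacobian = f$jacobian_to_original %||% NA_real_)
  })
  if (dplyr::n_distinct(rows$scale) > 1) {
    if (!correct_jacobian) {
      abort(paste("Fits are on different outcome scales; raw AICs are not",
                  "comparable. Use correct_jacobian = TRUE."))
    }
    if (anyNA(rows$jacobian)) {
      abort("Jacobian correction unavailable for at least one fit")
    }
    rows$aic <- rows$aic + 2 * rows$jacobian
  }
  rows |>
    dplyr::select(-"jacobian") |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic))
}

#' Assemble a joint-model fit from known parameters
#'
#' Builds a `joint_model_fit` directly from a parameter set, without
#' estimation. Useful in simulation studies (e.g. assessing the dynamic
#' prediction machinery under the true data-generating parameters); the
#' parameter covariance is zero, so predictions carry no parameter
#' uncertainty.
#'
#' @param beta Fixed effects (intercept, slope per time unit, then any
#'   longitudinal covariates, in `spec` order).
#' @param D 2x2 random-effect covariance.
#' @param sigma Residual SD.
#' @param lambda,shape Weibull baseline parameters.
#' @param alpha Current-value association.
#' @param gamma_S Survival covariate coefficients (in `spec` order).
#' @param alpha_deriv,alpha_int Optional further association terms.
#' @param spec A [jm_spec()].
#' @return A `joint_model_fit` with `converged = TRUE` and zero covariance.
#' @export
manual_joint_fit <- function(beta, D, sigma, lambda, shape = 1, alpha = 0,
                             gamma_S = numeric(0), alpha_deriv = 0,
                             alpha_int = 0, spec = jm_spec()) {
  has_cur <- "current_value" %in% spec$association
  has_der <- "first_derivative" %in% spec$association
  has_int <- !is.null(spec$association_by)
  pL <- length(beta)
  pS <- length(gamma_S)
  idx <- list(
    beta = seq_len(pL), log_sigma = pL + 1, chol = pL + 2:4,
    log_lambda = pL + 5, log_shape = pL + 6,
    gamma_S = if (pS) pL + 6 + seq_len(pS) else integer(0),
    alpha = if (has_cur) pL + 6 + pS + 1 else integer(0),
    alpha_deriv = if (has_der) pL + 6 + pS + has_cur + 1 else integer(0),
    alpha_int = if (has_int) pL + 6 + pS + has_cur + has_der + 1 else integer(0)
  )
  npar <- pL + 6 + pS + has_cur + has_der + has_int
  L <- t(chol(D))
  theta <- numeric(npar)
  theta[idx$beta] <- beta
  theta[idx$log_sigma] <- log(sigma)
  theta[idx$chol] <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  theta[idx$log_lambda] <- log(lambda)
  theta[idx$log_shape] <- log(shape)
  if (pS) theta[idx$gamma_S] <- gamma_S
  if (has_cur) theta[idx$alpha] <- alpha
  if (has_der) theta[idx$alpha_deriv] <- alpha_deriv
  if (has_int) theta[idx$alpha_int] <- alpha_int
  assoc <- tibble::tibble(term = "alpha_current", estimate = alpha,
                          std_error = 0)
  structure(list(
    beta = beta, D_hat = D, sigma2_hat = sigma^2,
    lambda = lambda, shape = shape, gamma_S = gamma_S,
    association = assoc, theta = theta,
    vcov = matrix(0, npar, npar), idx = idx,
    loglik = NA_real_, aic = NA_real_, k = npar, converged = TRUE,
    n_subjects = NA_integer_, n_events = NA_integer_, n_obs = NA_integer_,
    spec = spec, scale = spec$scale, time_unit = spec$time_unit,
    jacobian_to_original = NA_real_
  ), class = "joint_model_fit")
}

#' @export
print.joint_model_fit <- function(x, ...) {
  cat(sprintf(
    "<joint_model_fit> scale=%s, %s subjects, %s VTE events%s\n",
    x$scale, x$n_subjects, x$n_events,
    if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  logLik %.3f, AIC %.3f\n", x$loglik, x$aic))
  cat(sprintf("  Weibull baseline: shape %.4g, scale %.4g\n", x$shape,
              x$lambda))
  a <- x$association
  for (r in seq_len(nrow(a))) {
    cat(sprintf("  %s = %.4g (SE %.3g), HR = %.4g\n", a$term[r],
                a$estimate[r], a$std_error[r], exp(a$estimate[r])))
  }
  invisible(x)
}

#' @rdname fit_joint_model
#' @param x A `joint_model_fit`.
#' @param ... Unused.
#' @method tidy joint_model_fit
#' @export
tidy.joint_model_fit <- function(x, ...) {
  se_of <- function(j) if (anyNA(x$vcov)) NA_real_ else sqrt(max(x$vcov[j, j], 0))
  long <- tibble::tibble(
    component = "longitudinal",
    term = names(x$beta),
    estimate = unname(x$beta),
    std_error = purrr::map_dbl(x$idx$beta, se_of)
  )
  surv <- tibble::tibble(
    component = "survival",
    term = names(x$gamma_S) %||% character(0),
    estimate = unname(x$gamma_S),
    std_error = purrr::map_dbl(x$idx$gamma_S, se_of)
  )
  assoc <- dplyr::mutate(x$association, component = "association",
                         .before = 1)
  dplyr::bind_rows(long, surv, assoc) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pnorm(-abs(.data$statistic)),
      hazard_ratio = dplyr::if_else(.data$component %in%
                                      c("survival", "association"),
                                    exp(.data$estimate), NA_real_),
      conf_low = .data$estimate - qnorm(0.975) * .data$std_error,
      conf_high = .data$estimate + qnorm(0.975) * .data$std_error
    )
}

#' @rdname fit_joint_model
#' @method glance joint_model_fit
#' @export
glance.joint_model_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_events = x$n_events, n_obs = x$n_obs,
    df = x$k, logLik = x$loglik, AIC = x$aic, converged = x$converged,
    scale = x$scale,
    sigma = sqrt(x$sigma2_hat), shape = x$shape, lambda = x$lambda
  )
}

# central finite-difference gradient (relative step)
fd_gradient <- function(f, x, h_rel = 1e-6) {
  h <- h_rel * pmax(abs(x), 1)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

# central finite-difference Hessian (relative step)
fd_hessian <- function(f, x, h_rel = 1e-5) {
  k <- length(x)
  h <- h_rel * pmax(abs(x), 1)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) + f(x - ei) - 2 * f0) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}
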