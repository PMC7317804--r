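#' Simulate a longitudinal cohort with trajectory-linked VTE hazard
#'
#' Generates a synthetic oncology cohort under the data-generating process of
#' [cohort_params()]: latent subject-specific log2 D-dimer trajectories, VTE
#' times drawn by inverting the subject's cumulative hazard
#' \eqn{\Lambda_i(t) = \int_0^t \lambda p s^{p-1}
#' e^{x_i'\gamma_S + \alpha m_i(s)} ds} against an Exp(1) draw by bracketed
#' bisection (tolerance 1e-6 day), competing death from a constant hazard,
#' administrative censoring, and jittered ~monthly visits truncated at the
#' observed event/censoring time. A subject whose cumulative hazard at
#' maximum follow-up stays below the exponential draw is censored there.
#'
#' Baseline covariates (age, sex, BMI, tumor-site risk category, stage,
#' Khorana points) are drawn from study-like marginals; the true random
#' effects are returned in columns `true_b0`/`true_b1` for recovery tests.
#'
#' @param params A [cohort_params()] object.
#' @return A list with class `cohort`: `patients` (one row per subject) and
#'   `visits` (long format: `patient_id`, `time_days`, `ddimer_ugml`), both
#'   tibbles, plus the generating `params`.
#' @examples
#' coh <- simulate_cohort(paper_like_params(seed = 1))
#' dplyr::count(coh$patients, event_type)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_subjects
  if (n == 0) {
    return(new_cohort(empty_patients(), empty_visits(), params))
  }

  covs <- simulate_baseline_covariates(n)
  b <- draw_random_effects(n, params$D)
  etaL <- covariate_lp(covs, params$gamma_L)
  etaS <- covariate_lp(covs, params$gamma_S)
  a_i <- params$beta0 + etaL + b[, 1]   # latent intercept, log2 scale
  c_i <- params$beta1 + b[, 2]          # latent slope per day

  E <- rexp(n)
  t_vte <- sample_vte_times(E, params$weibull_scale, params$weibull_shape,
                            etaS, params$alpha, a_i, c_i,
                            params$max_followup_days)
  t_death <- if (params$death_hazard > 0) rexp(n, params$death_hazard) else rep(Inf, n)

  event_time <- pmin(t_vte, t_death, params$max_followup_days)
  event_type <- dplyr::case_when(
    t_vte <= t_death & t_vte <= params$max_followup_days ~ "VTE",
    t_death < t_vte & t_death <= params$max_followup_days ~ "death",
    .default = "censored"
  )

  patients <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    event_time_days = event_time,
    event_type = factor(event_type, levels = c("censored", "VTE", "death")),
    covs,
    true_b0 = b[, 1], true_b1 = b[, 2]
  )

  visits <- simulate_visits(patients$patient_id, event_time, a_i, c_i, params)
  new_cohort(patients, visits, params)
}

simulate_baseline_covariates <- function(n) {
  stage <- sample(c("local", "locally_advanced", "metastatic"), n,
                  replace = TRUE, prob = c(0.34, 0.22, 0.44))
  tibble::tibble(
    age = round(pmin(pmax(rnorm(n, 62, 10), 25), 90), 1),
    sex_female = rbinom(n, 1, 0.44),
    bmi = round(pmin(pmax(rnorm(n, 24.8, 4), 15), 45), 1),
    tumor_risk_category = factor(
      sample(c("low_moderate", "high", "very_high"), n, replace = TRUE,
             prob = c(0.14, 0.34, 0.52)),
      levels = c("low_moderate", "high", "very_high")
    ),
    stage = factor(stage, levels = c("local", "locally_advanced", "metastatic")),
    metastatic = as.integer(stage == "metastatic"),
    khorana_points = sample(0:4, n, replace = TRUE,
                            prob = c(0.08, 0.27, 0.45, 0.15, 0.05))
  )
}

draw_random_effects <- function(n, D) {
  L <- tryCatch(t(chol(D)), error = function(e) {
    # semi-definite (e.g. exactly-zero variance) handled via eigen square root
    e_ <- eigen(D, symmetric = TRUE)
    if (any(e_$values < -1e-10)) abort("D is not positive-semidefinite")
    e_$vectors %*% diag(sqrt(pmax(e_$values, 0)), 2)
  })
  matrix(rnorm(2 * n), n, 2) %*% t(L)
}

covariate_lp <- function(covs, gamma) {
  if (length(gamma) == 0) return(rep(0, nrow(covs)))
  missing_nm <- setdiff(names(gamma), names(covs))
  if (length(missing_nm)) {
    abort(paste("Unknown covariate(s) in coefficient vector:",
                paste(missing_nm, collapse = ", ")))
  }
  drop(as.matrix(covs[names(gamma)]) %*% gamma)
}

# Vectorised inversion of the cumulative VTE hazard against Exp(1) draws.
# H(t) = lam * exp(eta) * p * int_0^t s^(p-1) exp(alpha (a + c s)) ds,
# integral by 30-node Gauss-Legendre on [0, t]; bisection to ~1e-6 day.
sample_vte_times <- function(E, lam, p, eta, alpha, a, cc, tmax,
                             n_bisect = 45L, gl_nodes = 30L) {
  n <- length(E)
  gl <- pracma::gaussLegendre(gl_nodes, -1, 1)
  H_at <- function(t) {
    # t: n-vector; returns H_i(t_i)
    half <- t / 2
    S <- outer(half, gl$x + 1)           # n x K nodes on [0, t]
    integ <- p * S^(p - 1) * exp(alpha * (a + cc * S))
    lam * exp(eta) * half * drop(integ %*% gl$w)
  }
  Hmax <- H_at(rep(tmax, n))
  out <- rep(Inf, n)
  active <- Hmax >= E
  if (any(active)) {
    lo <- rep(0, sum(active)); hi <- rep(tmax, sum(active))
    Ea <- E[active]
    aa <- a[active]; cca <- cc[active]; etaa <- eta[active]
    Hsub <- function(t) {
      half <- t / 2
      S <- outer(half, gl$x + 1)
      integ <- p * S^(p - 1) * exp(alpha * (aa + cca * S))
      lam * exp(etaa) * half * drop(integ %*% gl$w)
    }
    for (k in seq_len(n_bisect)) {
      mid <- (lo + hi) / 2
      below <- Hsub(mid) < Ea
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[active] <- (lo + hi) / 2
  }
  out
}

simulate_visits <- function(ids, event_time, a_i, c_i, params) {
  n <- length(ids)
  k <- params$max_visits
  sched <- outer(rep(1, n), (seq_len(k) - 1) * params$visit_interval_days)
  if (params$visit_jitter_sd_days > 0 && k > 1) {
    sched[, -1] <- sched[, -1] +
      matrix(rnorm(n * (k - 1), 0, params$visit_jitter_sd_days), n, k - 1)
    sched[, -1][sched[, -1] < 0] <- 0
  }
  keep <- sweep(sched, 1, event_time, `<=`)
  if (params$missing_prob > 0) {
    keep <- keep & matrix(runif(n * k) >= params$missing_prob, n, k)
  }
  idx <- which(keep, arr.ind = TRUE)
  tvis <- sched[keep]
  eps <- rnorm(length(tvis), 0, params$sigma_eps)
  m <- a_i[idx[, 1]] + c_i[idx[, 1]] * tvis
  tibble::tibble(
    patient_id = ids[idx[, 1]],
    time_days = tvis,
    ddimer_ugml = 2^(m + eps)
  ) |>
    dplyr::arrange(.data$patient_id, .data$time_days)
}

new_cohort <- function(patients, visits, params) {
  structure(list(patients = patients, visits = visits, params = params),
            class = "cohort")
}

empty_patients <- function() {
  tibble::tibble(patient_id = character(), event_time_days = numeric(),
                 event_type = factor(character(),
                                     levels = c("censored", "VTE", "death")))
}

empty_visits <- function() {
  tibble::tibble(patient_id = character(), time_days = numeric(),
                 ddimer_ugml = numeric())
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d visits\n",
              nrow(x$patients), nrow(x$visits)))
  if (nrow(x$patients)) print(table(x$patients$event_type))
  invisible(x)
}

#' Simulate a two-cause constant-hazard cohort
#'
#' Benchmark generator for the competing-risk estimators: latent
#' cause-specific times are exponential with rates `lambda_vte` and
#' `lambda_death`; the observed time/type is the earlier of the two, subject
#' to administrative censoring. Under this process the cumulative incidence
#' of VTE has the closed form
#' \deqn{F_1(t) = \frac{\lambda_1}{\lambda_1+\lambda_2}
#'   \left(1 - e^{-(\lambda_1+\lambda_2)t}\right),}
#' used as an oracle in the test-suite.
#'
#' @param n Number of subjects.
#' @param lambda_vte,lambda_death Cause-specific constant rates per day
#'   (nonnegative, not both zero).
#' @param admin_censor_days Administrative censoring time (`Inf` to disable).
#' @param seed Integer seed or `NULL`.
#' @return A tibble of patients (`patient_id`, `event_time_days`,
#'   `event_type`).
#' @export
simulate_competing_constant_hazards <- function(n, lambda_vte, lambda_death,
                                                admin_censor_days = Inf,
                                                seed = NULL) {
  stopifnot(lambda_vte >= 0, lambda_death >= 0)
  if (n == 0) return(empty_patients())
  if (lambda_vte == 0 && lambda_death == 0) {
    abort("At least one of lambda_vte, lambda_death must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  t1 <- if (lambda_vte > 0) rexp(n, lambda_vte) else rep(Inf, n)
  t2 <- if (lambda_death > 0) rexp(n, lambda_death) else rep(Inf, n)
  tt <- pmin(t1, t2, admin_censor_days)
  type <- dplyr::case_when(
    t1 <= t2 & t1 <= admin_censor_days ~ "VTE",
    t2 < t1 & t2 <= admin_censor_days ~ "death",
    .default = "censored"
  )
  tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    event_time_days = tt,
    event_type = factor(type, levels = c("censored", "VTE", "death"))
  )
}

#' Simulate plain Gaussian random-intercept-and-slope trajectories
#'
#' Event-free longitudinal data for exercising the mixed model on its own:
#' \eqn{y_{ij} = (\mu_0 + b_{0i}) + (\mu_1 + b_{1i}) t_{ij} + \epsilon_{ij}}
#' on whatever scale the caller intends (`value` column; no positivity
#' constraint, no event process).
#'
#' @param n_subjects Number of subjects.
#' @param n_visits Visits per subject at `visit_interval_days` spacing
#'   starting at day 0.
#' @param visit_interval_days Spacing in days.
#' @param intercept_mean,intercept_sd Fixed mean and between-subject SD of
#'   the intercept.
#' @param slope_mean_per_day,slope_sd_per_day Fixed mean and between-subject
#'   SD of the slope, per day.
#' @param resid_sd Residual SD.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with `patient_id`, `time_days`, `value`, and the per-subject
#'   truths `true_intercept`, `true_slope_per_day`.
#' @export
simulate_lmm_trajectories <- function(n_subjects, n_visits = 7,
                                      visit_interval_days = 30,
                                      intercept_mean = 0, intercept_sd = 1,
                                      slope_mean_per_day = 0,
                                      slope_sd_per_day = 0,
                                      resid_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b0 <- rnorm(n_subjects, intercept_mean, intercept_sd)
  b1 <- rnorm(n_subjects, slope_mean_per_day, slope_sd_per_day)
  tidyr::expand_grid(
    i = seq_len(n_subjects),
    time_days = (seq_len(n_visits) - 1) * visit_interval_days
  ) |>
    dplyr::mutate(
      patient_id = sprintf("P%05d", .data$i),
      true_intercept = b0[.data$i],
      true_slope_per_day = b1[.data$i],
      value = .data$true_intercept + .data$true_slope_per_day * .data$time_days +
        rnorm(dplyr::n(), 0, resid_sd),
      i = NULL
    ) |>
    dplyr::relocate("patient_id")
}

#' Simulate a baseline-covariate Weibull cohort
#'
#' Benchmark generator for baseline Weibull proportional-hazards regression:
#' lognormal baseline D-dimer (parameterised by its median and the SD of its
#' log2), event times Weibull with hazard
#' \eqn{h(t) = \lambda_0 p t^{p-1} e^{\beta \log_2(\mathrm{ddimer})}}, and
#' administrative censoring. The baseline rate is calibrated with
#' [calibrate_baseline_rate()] to the requested marginal incidence.
#'
#' @param n Number of subjects.
#' @param coef_per_log2 True log-hazard coefficient per doubling of baseline
#'   D-dimer.
#' @param median_ddimer Median of the lognormal baseline D-dimer (µg/mL).
#' @param sd_log2 SD of log2 baseline D-dimer.
#' @param shape Weibull shape.
#' @param target_incidence Marginal event probability by `censor_days` the
#'   baseline rate is calibrated to.
#' @param censor_days Administrative censoring time.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with `patient_id`, `event_time_days`, `event_type`,
#'   `baseline_ddimer`.
#' @export
simulate_baseline_weibull_cohort <- function(n, coef_per_log2 = 0.5481,
                                             median_ddimer = 0.97,
                                             sd_log2 = 1.4, shape = 1,
                                             target_incidence = 0.12,
                                             censor_days = 250, seed = NULL) {
  mu <- log2(median_ddimer)
  lam0 <- calibrate_baseline_rate(target_incidence, censor_days,
                                  coef_per_log2, mu, sd_log2)
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, mu, sd_log2)
  # Weibull with H(t) = lam0 e^(beta x) t^shape  =>  T = (E / (lam0 e^(bx)))^(1/shape)
  E <- rexp(n)
  tt <- (E / (lam0 * exp(coef_per_log2 * x)))^(1 / shape)
  obs <- pmin(tt, censor_days)
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    event_time_days = obs,
    event_type = factor(ifelse(tt <= censor_days, "VTE", "censored"),
                        levels = c("censored", "VTE", "death")),
    baseline_ddimer = 2^x
  )
}

#' Write a simulated cohort to delimited text
#'
#' Writes `visits.csv` (`patient_id,time_days,ddimer_ugml`), `patients.csv`
#' (`patient_id,event_time_days,event_type,` covariate columns), and a
#' `params.json` sidecar recording the true generating parameters, into
#' `dir`.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    visits = file.path(dir, "visits.csv"),
    patients = file.path(dir, "patients.csv"),
    params = file.path(dir, "params.json")
  )
  utils::write.csv(cohort$visits, paths[["visits"]], row.names = FALSE)
  utils::write.csv(cohort$patients, paths[["patients"]], row.names = FALSE)
  pj <- unclass(cohort$params)
  pj$D <- as.vector(pj$D)   # row-major 2x2 flattened (symmetric)
  jsonlite::write_json(pj, paths[["params"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory containing `visits.csv` and `patients.csv`.
#' @return A list with `visits` and `patients` tibbles.
#' @export
read_cohort <- function(dir) {
  visits <- tibble::as_tibble(utils::read.csv(file.path(dir, "visits.csv")))
  patients <- tibble::as_tibble(utils::read.csv(file.path(dir, "patients.csv")))
  patients$event_type <- factor(patients$event_type,
                                levels = c("censored", "VTE", "death"))
  list(visits = visits, patients = patients)
}
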