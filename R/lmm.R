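#' Fit the random-intercept-and-slope mixed model to biomarker trajectories
#'
#' Maximum-likelihood (not REML) linear mixed model
#' \eqn{y_{ij} = x_{ij}'\beta + b_{0i} + b_{1i} t_{ij} + \epsilon_{ij}} with
#' an unstructured 2x2 random-effect covariance, fitted via [lme4::lmer()].
#' ML is used throughout so that AICs are comparable across fixed-effect
#' structures. With `group_by_event = TRUE` the fixed effects include a
#' prospective-VTE-status main effect and a status-by-time interaction, so
#' each group has its own slope (a descriptive analysis that conditions on
#' the future; the joint model is the inferential product).
#'
#' @param data An [build_dataset()] `analysis_dataset`, or a plain data frame
#'   with `patient_id`, `time_days` and the response column named by
#'   `response`.
#' @param scale Response scale: `"original_ugml"`, `"log2"`, or
#'   `"natural_log"`. For an `analysis_dataset` this selects/derives the
#'   response; for a plain data frame it is a label used by back-transforms.
#' @param group_by_event Add prospective event-status (VTE vs no VTE) main
#'   and interaction terms.
#' @param covariates Character vector of baseline covariate columns (taken
#'   from the patient table) entering the fixed effects.
#' @param time_unit `"months"` (30-day) or `"days"` for the time variable.
#' @param time_degree 1 for linear time (default); 3 adds squared and cubic
#'   fixed-effect terms (sensitivity analysis; the random effect stays
#'   linear).
#' @param response Response column name when `data` is a plain data frame.
#' @return An object of class `longitudinal_fit`.
#' @examples
#' coh <- simulate_cohort(paper_like_params(seed = 1))
#' ds <- build_dataset(coh$visits, coh$patients)
#' fit <- fit_lmm(ds, scale = "original_ugml", group_by_event = TRUE)
#' tidy(fit)
#' @export
fit_lmm <- function(data, scale = c("log2", "original_ugml", "natural_log"),
                    group_by_event = FALSE, covariates = NULL,
                    time_unit = c("months", "days"), time_degree = 1,
                    response = "value") {
  scale <- match.arg(scale)
  time_unit <- match.arg(time_unit)
  stopifnot(time_degree %in% c(1, 2, 3))

  if (inherits(data, "analysis_dataset")) {
    df <- model_frame(data, scale, time_unit)
    if (!is.null(covariates)) {
      df <- dplyr::left_join(
        df, dplyr::select(data$patients, "patient_id",
                          dplyr::all_of(covariates)),
        by = "patient_id")
    }
  } else {
    df <- tibble::as_tibble(data)
    stopifnot(all(c("patient_id", "time_days", response) %in% names(df)))
    df$y <- df[[response]]
    df$time <- if (time_unit == "months") df$time_days / 30 else df$time_days
    if (group_by_event) stopifnot("event_type" %in% names(df))
  }
  df <- dplyr::filter(df, !is.na(.data$y))
  if (dplyr::n_distinct(df$patient_id) < 2) {
    abort("Need at least 2 subjects with visits")
  }
  if (var(df$time) == 0) abort("No variation in visit times")

  terms <- "time"
  if (time_degree >= 2) terms <- c(terms, "I(time^2)")
  if (time_degree >= 3) terms <- c(terms, "I(time^3)")
  if (group_by_event) {
    df$vte_group <- factor(ifelse(df$event_type == "VTE", "VTE", "no_VTE"),
                           levels = c("no_VTE", "VTE"))
    terms <- c("vte_group", terms, "vte_group:time")
  }
  terms <- c(terms, covariates)
  form <- as.formula(paste("y ~", paste(terms, collapse = " + "),
                           "+ (1 + time | patient_id)"))

  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        abort(paste("Mixed model failed to converge:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (lme4::isSingular(fit)) {
    warn("Random-effect covariance estimate is singular (boundary fit)")
  }

  vc <- lme4::VarCorr(fit)[["patient_id"]]
  D_hat <- matrix(as.numeric(vc), 2, 2,
                  dimnames = list(c("intercept", "time"),
                                  c("intercept", "time")))
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  ll <- logLik(fit)

  structure(list(
    fixed_effects = tibble::tibble(
      term = names(beta),
      estimate = unname(beta),
      std_error = sqrt(diag(V))
    ),
    vcov_fixed = V,
    D_hat = D_hat,
    sigma2_hat = unname(lme4::getME(fit, "sigma"))^2,
    loglik = as.numeric(ll),
    df = attr(ll, "df"),
    aic = AIC(fit),
    scale = scale, time_unit = time_unit, time_degree = time_degree,
    group_by_event = group_by_event, covariates = covariates,
    n_subjects = dplyr::n_distinct(df$patient_id),
    n_obs = nrow(df),
    jacobian_to_original = if ("ddimer_ugml" %in% names(df)) {
      switch(scale,
             log2 = sum(log(df$ddimer_ugml * log(2))),
             natural_log = sum(log(df$ddimer_ugml)),
             original_ugml = 0)
    } else NA_real_,
    lmer_fit = fit,
    frame = df
  ), class = "longitudinal_fit")
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf(
    "<longitudinal_fit> scale=%s, time in %s, %d subjects / %d obs\n",
    x$scale, x$time_unit, x$n_subjects, x$n_obs))
  cat(sprintf("  logLik %.2f, AIC %.2f, sigma %.4g, sd(b0) %.4g, sd(b1) %.4g\n",
              x$loglik, x$aic, sqrt(x$sigma2_hat), sqrt(x$D_hat[1, 1]),
              sqrt(x$D_hat[2, 2])))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `longitudinal_fit`.
#' @param ... Unused.
#' @method tidy longitudinal_fit
#' @export
tidy.longitudinal_fit <- function(x, ...) {
  x$fixed_effects |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pnorm(-abs(.data$statistic)),
      conf_low = .data$estimate - qnorm(0.975) * .data$std_error,
      conf_high = .data$estimate + qnorm(0.975) * .data$std_error
    )
}

#' @rdname fit_lmm
#' @method glance longitudinal_fit
#' @export
glance.longitudinal_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_obs = x$n_obs, df = x$df,
    logLik = x$loglik, AIC = x$aic, sigma = sqrt(x$sigma2_hat),
    sd_intercept = sqrt(x$D_hat[1, 1]), sd_slope = sqrt(x$D_hat[2, 2]),
    scale = x$scale, time_unit = x$time_unit
  )
}

# linear-combination vector picking out the slope of `group` (or the overall
# slope when the fit has no grouping)
slope_lincomb <- function(fit, group = NULL) {
  nm <- fit$fixed_effects$term
  l <- setNames(numeric(length(nm)), nm)
  l["time"] <- 1
  if (!is.null(group) && group != "no_VTE") {
    int <- paste0("vte_group", group, ":time")
    if (!int %in% nm) abort(paste("Group not in fit:", group))
    l[int] <- 1
  }
  l
}

#' Per-group trajectory slopes from a grouped fit
#'
#' @param fit A `longitudinal_fit` with `group_by_event = TRUE` (for an
#'   ungrouped fit, a single `"all"` row is returned).
#' @return Tibble with `group`, `slope_per_unit` (per fitted time unit),
#'   `std_error`, `conf_low`, `conf_high`, `p_value`.
#' @export
group_slopes <- function(fit) {
  stopifnot(inherits(fit, "longitudinal_fit"))
  groups <- if (fit$group_by_event) c("no_VTE", "VTE") else "all"
  purrr::map_dfr(groups, function(g) {
    l <- slope_lincomb(fit, if (fit$group_by_event) g else NULL)
    est <- sum(l * fit$fixed_effects$estimate)
    se <- sqrt(drop(t(l) %*% fit$vcov_fixed %*% l))
    tibble::tibble(
      group = g, slope_per_unit = est, std_error = se,
      conf_low = est - qnorm(0.975) * se,
      conf_high = est + qnorm(0.975) * se,
      p_value = 2 * pnorm(-abs(est / se))
    )
  })
}

#' Wald contrast between two groups' trajectory slopes
#'
#' Difference of per-group slopes (per fitted time unit) with a delta-method
#' standard error from the fixed-effect covariance.
#'
#' @param fit A `longitudinal_fit` containing a group-by-time interaction.
#' @param group_a,group_b Group labels (`"VTE"`, `"no_VTE"`); the contrast is
#'   `group_a - group_b`.
#' @return One-row tibble: `estimate`, `std_error`, `conf_low`, `conf_high`,
#'   `p_value`.
#' @export
slope_contrast <- function(fit, group_a = "VTE", group_b = "no_VTE") {
  stopifnot(inherits(fit, "longitudinal_fit"))
  if (!fit$group_by_event) {
    abort("slope_contrast() needs a fit with group_by_event = TRUE")
  }
  l <- slope_lincomb(fit, group_a) - slope_lincomb(fit, group_b)
  est <- sum(l * fit$fixed_effects$estimate)
  se <- sqrt(drop(t(l) %*% fit$vcov_fixed %*% l))
  tibble::tibble(
    estimate = est, std_error = se,
    conf_low = est - qnorm(0.975) * se,
    conf_high = est + qnorm(0.975) * se,
    p_value = 2 * pnorm(-abs(est / se))
  )
}

#' Percent change in D-dimer per 30-day month from a log-scale fit
#'
#' Back-transforms per-month slopes of a log-scale trajectory fit to percent
#' change per month: `100 * (exp(slope_ln_per_month) - 1)`, where a log2
#' slope is first multiplied by `ln 2`. CI endpoints are transformed the
#' same way.
#'
#' @param fit A `longitudinal_fit` on the `log2` or `natural_log` scale.
#' @return Tibble with `group`, `pct_per_month`, `conf_low`, `conf_high`.
#' @export
percent_change_per_month <- function(fit) {
  stopifnot(inherits(fit, "longitudinal_fit"))
  if (fit$scale == "original_ugml") {
    abort("Percent change per month requires a log-scale fit")
  }
  per_month <- if (fit$time_unit == "months") 1 else 30
  to_ln <- if (fit$scale == "log2") log(2) else 1
  group_slopes(fit) |>
    dplyr::transmute(
      group = .data$group,
      pct_per_month = 100 * (exp(.data$slope_per_unit * per_month * to_ln) - 1),
      conf_low = 100 * (exp(.data$conf_low * per_month * to_ln) - 1),
      conf_high = 100 * (exp(.data$conf_high * per_month * to_ln) - 1)
    )
}
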