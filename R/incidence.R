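#' One-minus-Kaplan-Meier incidence curve
#'
#' Product-limit estimator of the incidence of one cause, treating the
#' competing cause as right-censoring (the "naive" estimator: with competing
#' deaths present it overestimates the true cumulative incidence). Pointwise
#' 95% CIs are Greenwood-based on the log(-log) scale.
#'
#' @param patients Tibble with `event_time_days` and `event_type`
#'   (`censored` / `VTE` / `death`).
#' @param cause Cause counted as the event; the other cause is censored.
#' @return An `incidence_curve`: a tibble (`time`, `estimate`, `conf_low`,
#'   `conf_high`, `n_risk`, `n_event`) with attributes `method`
#'   (`"one_minus_km"`) and `cause`.
#' @export
kaplan_meier <- function(patients, cause = c("VTE", "death")) {
  cause <- match.arg(cause)
  stopifnot(nrow(patients) >= 1)
  status <- as.integer(patients$event_type == cause)
  if (!any(status)) {
    warn(sprintf("No %s events; incidence curve is identically zero", cause))
    return(new_incidence_curve(
      tibble::tibble(time = max(patients$event_time_days), estimate = 0,
                     conf_low = 0, conf_high = 0,
                     n_risk = nrow(patients), n_event = 0L),
      method = "one_minus_km", cause = cause))
  }
  sf <- survival::survfit(
    survival::Surv(patients$event_time_days, status) ~ 1,
    conf.type = "log-log")
  new_incidence_curve(
    tibble::tibble(
      time = sf$time,
      estimate = 1 - sf$surv,
      conf_low = 1 - sf$upper,
      conf_high = 1 - sf$lower,
      n_risk = sf$n.risk,
      n_event = sf$n.event
    ),
    method = "one_minus_km", cause = cause)
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric cumulative incidence of VTE and of competing death,
#' \eqn{F_k(t) = \sum_{t_j \le t} S(t_j^-)\, d_{kj}/n_j} with \eqn{S} the
#' all-cause Kaplan-Meier, computed via the multi-state machinery of
#' [survival::survfit()]. Pointwise 95% CIs by the delta method on
#' \eqn{\log(-\log F_k)}.
#'
#' @inheritParams kaplan_meier
#' @return Named list with `VTE` and `death` elements, each an
#'   `incidence_curve` (method `"aalen_johansen"`), plus `overall_survival`,
#'   a tibble of the all-cause KM at the same times.
#' @export
aalen_johansen <- function(patients) {
  stopifnot(nrow(patients) >= 1)
  f <- factor(as.character(patients$event_type),
              levels = c("censored", "VTE", "death"))
  if (all(f == "censored")) {
    warn("No events; both incidence curves are identically zero")
  }
  sf <- survival::survfit(survival::Surv(patients$event_time_days, f) ~ 1)
  states <- sf$states
  curves <- purrr::map(c(VTE = "VTE", death = "death"), function(st) {
    j <- match(st, states)
    est <- if (is.na(j)) rep(0, length(sf$time)) else sf$pstate[, j]
    se <- if (is.na(j)) rep(0, length(sf$time)) else sf$std.err[, j]
    ci <- loglog_ci(est, se)
    new_incidence_curve(
      tibble::tibble(
        time = sf$time, estimate = est,
        conf_low = ci$lo, conf_high = ci$hi,
        n_risk = sf$n.risk[, 1],
        n_event = if (is.na(j)) rep(0L, length(sf$time))
                  else sf$n.event[, j]
      ),
      method = "aalen_johansen", cause = st)
  })
  s0 <- match("(s0)", states)
  curves$overall_survival <- tibble::tibble(
    time = sf$time,
    survival = if (is.na(s0)) rep(1, length(sf$time)) else sf$pstate[, s0]
  )
  curves
}

# delta-method CI on log(-log F); degenerate at F = 0
loglog_ci <- function(est, se) {
  lo <- hi <- est
  ok <- est > 0 & est < 1 & se > 0
  z <- qnorm(0.975)
  g_se <- se[ok] / (est[ok] * abs(log(est[ok])))
  lo[ok] <- est[ok]^exp(z * g_se)
  hi[ok] <- est[ok]^exp(-z * g_se)
  list(lo = pmin(lo, est), hi = pmax(hi, est))
}

new_incidence_curve <- function(tbl, method, cause) {
  structure(tbl, class = c("incidence_curve", class(tbl)),
            method = method, cause = cause)
}

#' Step-function lookup on an incidence curve
#'
#' @param curve An `incidence_curve`.
#' @param t Times at which to evaluate the (right-continuous) estimate.
#' @return Numeric vector of estimates at `t` (0 before the first event).
#' @export
incidence_at <- function(curve, t) {
  stopifnot(inherits(curve, "incidence_curve"))
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 0, curve$estimate[pmax(idx, 1)])
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat(sprintf("<incidence_curve> %s, cause %s, %d time points, final %.4f\n",
              attr(x, "method"), attr(x, "cause"), nrow(x),
              if (nrow(x)) x$estimate[nrow(x)] else 0))
  NextMethod()
}

#' Plot an incidence curve
#'
#' @param object An `incidence_curve`.
#' @param ... Unused.
#' @return A ggplot: step curve with a pointwise 95% band.
#' @method autoplot incidence_curve
#' @export
autoplot.incidence_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  # expand to a piecewise-constant path so the band follows the steps
  step_df <- dplyr::bind_rows(
    df,
    dplyr::mutate(df, time = dplyr::lead(.data$time, default = max(df$time)))
  ) |>
    dplyr::arrange(.data$time, .data$estimate)
  ggplot2::ggplot(step_df,
                  ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Days from baseline",
      y = sprintf("Cumulative incidence of %s", attr(object, "cause")),
      title = sprintf("%s estimate",
                      switch(attr(object, "method"),
                             one_minus_km = "1 - Kaplan-Meier",
                             aalen_johansen = "Aalen-Johansen"))
    ) +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::theme_minimal()
}
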