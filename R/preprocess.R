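#' Build the analysis dataset from raw visit and patient tables
#'
#' Validates and filters raw tables into the analysis set used by all model
#' fits: patients with *any* D-dimer measurement above `ddimer_cap` are
#' excluded entirely (the cap mirrors the analysis rule that one extreme
#' patient with D-dimer > 40 µg/mL destabilises estimation), values below
#' the limit-of-detection floor are raised to `lod_floor` before the log2
#' transform, and a `log2_ddimer` column is added. Times are kept in days;
#' if `time_unit = "months"` a `time` column in 30-day months is added
#' alongside (conversion happens here, once).
#'
#' @param visits Data frame with `patient_id`, `time_days`, `ddimer_ugml`.
#' @param patients Data frame with `patient_id`, `event_time_days`,
#'   `event_type` (factor/character in `censored`, `VTE`, `death`) and any
#'   baseline covariate columns.
#' @param ddimer_cap Exclusion threshold in µg/mL (per patient).
#' @param lod_floor Floor applied to D-dimer before the log transform.
#' @param time_unit `"days"` or `"months"` (30-day months) for the
#'   model-facing `time` column.
#' @return An object of class `analysis_dataset`: list with tibbles `visits`
#'   (including `log2_ddimer` and `time`), `patients`, a tibble `exclusions`
#'   (`patient_id`, `reason`), and `time_unit`.
#' @examples
#' coh <- simulate_cohort(paper_like_params(seed = 1))
#' ds <- build_dataset(coh$visits, coh$patients)
#' ds$exclusions
#' @export
build_dataset <- function(visits, patients, ddimer_cap = 40, lod_floor = 0.1,
                          time_unit = c("days", "months")) {
  time_unit <- match.arg(time_unit)
  visits <- tibble::as_tibble(visits)
  patients <- tibble::as_tibble(patients)
  stopifnot(nrow(patients) > 0)
  req_v <- c("patient_id", "time_days", "ddimer_ugml")
  req_p <- c("patient_id", "event_time_days", "event_type")
  if (!all(req_v %in% names(visits))) {
    abort(paste("visits must contain columns:", paste(req_v, collapse = ", ")))
  }
  if (!all(req_p %in% names(patients))) {
    abort(paste("patients must contain columns:", paste(req_p, collapse = ", ")))
  }
  if (any(visits$time_days < 0)) abort("Negative visit times")
  if (any(visits$ddimer_ugml < 0)) {
    abort(paste("Negative D-dimer values for:",
                paste(unique(visits$patient_id[visits$ddimer_ugml < 0]),
                      collapse = ", ")))
  }
  if (!is.factor(patients$event_type)) {
    patients$event_type <- factor(patients$event_type,
                                  levels = c("censored", "VTE", "death"))
  }
  if (anyNA(patients$event_type)) abort("Invalid event_type values")
  orphans <- setdiff(visits$patient_id, patients$patient_id)
  if (length(orphans)) {
    abort(paste("Orphan visits with no matching patient:",
                paste(orphans, collapse = ", ")))
  }

  over <- visits |>
    dplyr::filter(.data$ddimer_ugml > ddimer_cap) |>
    dplyr::distinct(.data$patient_id)
  exclusions <- tibble::tibble(
    patient_id = over$patient_id,
    reason = sprintf("D-dimer > %g ug/mL", ddimer_cap)
  )
  visits <- visits |>
    dplyr::filter(!.data$patient_id %in% exclusions$patient_id) |>
    dplyr::mutate(
      ddimer_ugml = pmax(.data$ddimer_ugml, lod_floor),
      log2_ddimer = log2(.data$ddimer_ugml),
      time = if (time_unit == "months") .data$time_days / 30 else .data$time_days
    )
  patients <- dplyr::filter(patients,
                            !.data$patient_id %in% exclusions$patient_id)

  structure(
    list(visits = visits, patients = patients, exclusions = exclusions,
         time_unit = time_unit, ddimer_cap = ddimer_cap,
         lod_floor = lod_floor),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("<analysis_dataset> %d patients, %d visits (time unit: %s)\n",
              nrow(x$patients), nrow(x$visits), x$time_unit))
  if (nrow(x$exclusions)) {
    cat(sprintf("  excluded %d patient(s): %s\n", nrow(x$exclusions),
                paste(x$exclusions$patient_id, collapse = ", ")))
  }
  invisible(x)
}

# model-facing response column for a given scale
response_column <- function(scale) {
  switch(scale,
         original_ugml = "ddimer_ugml",
         log2 = "log2_ddimer",
         natural_log = "log_ddimer",
         abort(paste("Unknown scale:", scale)))
}

# visits joined with event info, with the response for `scale` materialised
model_frame <- function(data, scale, time_unit) {
  stopifnot(inherits(data, "analysis_dataset"))
  v <- data$visits |>
    dplyr::mutate(log_ddimer = .data$log2_ddimer * log(2)) |>
    dplyr::left_join(
      dplyr::select(data$patients, "patient_id", "event_time_days",
                    "event_type"),
      by = "patient_id"
    )
  v$time <- if (time_unit == "months") v$time_days / 30 else v$time_days
  v$y <- v[[response_column(scale)]]
  v
}
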