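#' Run the full analysis pipeline
#'
#' Ties the stages together reproducibly: simulate (or ingest) a cohort,
#' build the analysis dataset, fit the descriptive mixed models (per-group
#' slopes on the µg/mL and log scales), estimate cumulative incidence
#' (Aalen-Johansen and 1-KM), fit the joint models (log2 and original
#' scales), and issue dynamic predictions for selected patients. All outputs
#' are tidy CSVs / JSON fit records under `out_dir`; every CSV carries a
#' provenance header (`# config_hash`, `# seed`). All randomness flows from
#' the single root `seed` (simulation uses `seed`, predictions `seed + 1`).
#'
#' @param config A named list (or path to a YAML file with the same
#'   structure): fields `out_dir`, `seed`, and optionally `simulate` (a list
#'   of [cohort_params()] arguments; omit to supply `input` with `visits`
#'   and `patients` CSV paths), `preprocess` (`ddimer_cap`, `lod_floor`),
#'   `stages` (subset of `lmm`, `incidence`, `joint`, `predict`),
#'   `predict` (`n_patients`, `landmark_days`, `horizon_days`, `draws`).
#' @return Invisibly, a list of the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("lmm", "incidence", "joint", "predict")
  bad <- setdiff(stages, c("lmm", "incidence", "joint", "predict"))
  if (length(bad)) abort(paste("Unknown stage(s):", paste(bad, collapse = ", ")))
  pre <- config$preprocess %||% list()
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  results <- list()
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat(sprintf("jointtraj pipeline\nseed: %d\nconfig_hash: %s\nR: %s\n",
              seed, hash, R.version.string), file = logf)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s (earlier outputs kept in %s)",
                    name, conditionMessage(e), out_dir))
    })
  }

  # ---- data ----
  raw <- run_stage("simulate", {
    if (!is.null(config$input)) {
      list(visits = tibble::as_tibble(utils::read.csv(config$input$visits)),
           patients = {
             p <- tibble::as_tibble(utils::read.csv(config$input$patients))
             p$event_type <- factor(p$event_type,
                                    levels = c("censored", "VTE", "death"))
             p
           })
    } else {
      pars <- do.call(cohort_params, modifyList(
        as.list(unclass(paper_like_params()))[
          setdiff(names(unclass(paper_like_params())), "seed")],
        config$simulate %||% list()))
      pars$seed <- seed
      coh <- simulate_cohort(pars)
      write_cohort(coh, out_dir)
      logline("simulated %d patients / %d visits", nrow(coh$patients),
              nrow(coh$visits))
      coh[c("visits", "patients")]
    }
  })

  ds <- run_stage("preprocess", build_dataset(
    raw$visits, raw$patients,
    ddimer_cap = pre$ddimer_cap %||% 40,
    lod_floor = pre$lod_floor %||% 0.1))
  results$dataset <- ds
  logline("analysis set: %d patients, %d visits, %d excluded",
          nrow(ds$patients), nrow(ds$visits), nrow(ds$exclusions))

  # ---- descriptive mixed models (per-group slope table) ----
  if ("lmm" %in% stages) run_stage("lmm", {
    fit_ug <- fit_lmm(ds, scale = "original_ugml", group_by_event = TRUE,
                      time_unit = "months")
    fit_ln <- fit_lmm(ds, scale = "natural_log", group_by_event = TRUE,
                      time_unit = "months")
    slopes <- dplyr::bind_rows(
      dplyr::mutate(group_slopes(fit_ug), scale = "ugml_per_month"),
      dplyr::mutate(slope_contrast(fit_ug), group = "difference",
                    scale = "ugml_per_month", slope_per_unit = .data$estimate),
      dplyr::mutate(
        percent_change_per_month(fit_ln) |>
          dplyr::rename(slope_per_unit = "pct_per_month"),
        scale = "pct_per_month")
    ) |>
      dplyr::select("group", "scale", "slope_per_unit", "conf_low",
                    "conf_high", dplyr::any_of("p_value"))
    write_with_provenance(slopes, file.path(out_dir, "trajectory_slopes.csv"),
                          hash, seed)
    results$lmm <- list(original = fit_ug, natural_log = fit_ln,
                        slopes = slopes)
  })

  # ---- incidence ----
  if ("incidence" %in% stages) run_stage("incidence", {
    aj <- aalen_johansen(ds$patients)
    km <- kaplan_meier(ds$patients)
    curves <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(aj$VTE), method = "aalen_johansen",
                    cause = "VTE"),
      dplyr::mutate(tibble::as_tibble(aj$death), method = "aalen_johansen",
                    cause = "death"),
      dplyr::mutate(tibble::as_tibble(km), method = "one_minus_km",
                    cause = "VTE")
    )
    write_with_provenance(curves, file.path(out_dir, "incidence.csv"),
                          hash, seed)
    results$incidence <- list(aalen_johansen = aj, one_minus_km = km)
  })

  # ---- joint models ----
  if ("joint" %in% stages) run_stage("joint", {
    fits <- list(
      log2 = fit_joint_model(ds, jm_spec(scale = "log2")),
      original_ugml = fit_joint_model(ds, jm_spec(scale = "original_ugml"))
    )
    assoc <- purrr::imap_dfr(fits, function(f, sc) {
      tidy(f) |>
        dplyr::filter(.data$component == "association") |>
        dplyr::mutate(scale = sc, aic = f$aic, converged = f$converged)
    })
    write_with_provenance(assoc, file.path(out_dir, "association.csv"),
                          hash, seed)
    jsonlite::write_json(
      purrr::map(fits, function(f) list(
        scale = f$scale, loglik = f$loglik, aic = f$aic,
        converged = f$converged, coefficients = tidy(f))),
      file.path(out_dir, "joint_fits.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$joint <- fits
  })

  # ---- dynamic predictions ----
  if ("predict" %in% stages) run_stage("predict", {
    if (is.null(results$joint)) {
      abort("the 'predict' stage needs the 'joint' stage")
    }
    fit <- results$joint$log2
    pc <- config$predict %||% list()
    landmark <- pc$landmark_days %||% 120
    horizon <- pc$horizon_days %||% (landmark + 180)
    ids <- pc$patient_ids %||% {
      alive <- ds$patients |>
        dplyr::filter(.data$event_time_days > landmark)
      head(alive$patient_id, pc$n_patients %||% 2)
    }
    preds <- purrr::map_dfr(ids, function(id) {
      h <- patient_history(ds, id, up_to_days = landmark)
      grid <- seq(landmark, horizon, length.out = 13)
      pr <- predict_risk(fit, h, landmark_s = landmark, horizons = grid,
                         n_mc_draws = pc$draws %||% 500,
                         seed = seed + 1L, force = TRUE)
      dplyr::mutate(tibble::as_tibble(pr), patient_id = id, .before = 1)
    })
    write_with_provenance(preds, file.path(out_dir, "predictions.csv"),
                          hash, seed)
    results$predictions <- preds
  })

  logline("done: %s", paste(stages, collapse = ", "))
  invisible(c(results, list(out_dir = out_dir, config_hash = hash)))
}

# CSV with a provenance comment header
write_with_provenance <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance headers
#'
#' @param path CSV path written by [run_pipeline()].
#' @return A tibble.
#' @export
read_pipeline_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
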