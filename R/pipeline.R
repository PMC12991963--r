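#' Pipeline configuration
#'
#' Collects every knob of [run_pipeline()] in one validated list. A
#' configuration can also be read from a YAML file with
#' [read_pipeline_config()]; unnamed fields fall back to these defaults.
#'
#' @param input Path of a survey CSV, or `NULL` to simulate from `preset`.
#' @param preset Simulation preset name (see [scenario_preset()]) used when
#'   `input` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param ci_level Confidence level used throughout.
#' @param transformed Apply the Hellinger transformation before diversity
#'   metrics (default `TRUE`).
#' @param alpha_metrics,beta_components Metrics to fit and contrast.
#' @param seed Integer seed for simulation.
#' @param sim Named list of overrides passed to [scenario_preset()].
#' @param verbose Emit progress messages and write a run log.
#' @return A list of class `exclo_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = "homogenization",
                            out_dir = "exclodiv-out", ci_level = 0.95,
                            transformed = TRUE,
                            alpha_metrics = c("richness", "shannon",
                                              "inv_simpson"),
                            beta_components = c("total", "balanced",
                                                "gradient"),
                            seed = 1L, sim = list(), verbose = TRUE) {
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("Invalid configuration field `ci_level`: must be in (0, 1).",
          class = "exclodiv_config_error")
  }
  if (is.null(input) &&
      !(is.character(preset) && length(preset) == 1 &&
        preset %in% c("null", "homogenization", "release_only"))) {
    abort("Invalid configuration field `preset`: see `scenario_preset()`.",
          class = "exclodiv_config_error")
  }
  bad <- setdiff(alpha_metrics, c("richness", "shannon", "inv_simpson"))
  if (length(bad) > 0) {
    abort(sprintf("Invalid configuration field `alpha_metrics`: unknown metric(s) %s.",
                  paste(bad, collapse = ", ")),
          class = "exclodiv_config_error")
  }
  bad <- setdiff(beta_components, c("total", "balanced", "gradient"))
  if (length(bad) > 0) {
    abort(sprintf("Invalid configuration field `beta_components`: unknown component(s) %s.",
                  paste(bad, collapse = ", ")),
          class = "exclodiv_config_error")
  }
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(input = input, preset = preset, out_dir = out_dir,
         ci_level = ci_level, transformed = transformed,
         alpha_metrics = alpha_metrics, beta_components = beta_components,
         seed = as.integer(seed), sim = sim, verbose = isTRUE(verbose)),
    class = "exclo_pipeline_config"
  )
}

#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pipeline configuration field(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "exclodiv_config_error")
  }
  do.call(pipeline_config, vals)
}

#' Run the full exclosure-diversity pipeline
#'
#' End-to-end orchestration: obtain a survey (read + validate a CSV, or
#' simulate from a preset), then write to the output directory
#'
#' * `survey.csv` — the analysed survey (simulated runs only),
#' * `alpha_diversity.csv` — per-plot alpha records,
#' * `beta_diversity.csv` — multiple-site partitions with jackknife columns,
#' * `model_fits.csv` — one row per site x metric x coefficient, with the
#'   component-gating flag,
#' * `residuals.csv` — model residuals for diagnostics,
#' * `contrasts.csv` — pairwise cross-site interaction contrasts,
#' * `manifest.json` — configuration, seed and session versions,
#' * `run.log` — stage log (when `verbose`).
#'
#' Stage outputs equal what the module functions return when called manually
#' on the same survey. Sites whose models cannot be fitted are skipped with
#' a logged warning; the rest of the run proceeds.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the survey, the five result tibbles and
#'   the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "exclo_pipeline_config")) {
    abort("`config` must come from `pipeline_config()`.",
          class = "exclodiv_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), line))
    if (config$verbose) inform(line)
  }

  if (is.null(config$input)) {
    say("Simulating survey from preset '%s' (seed %d).", config$preset,
        config$seed)
    sim_cfg <- do.call(scenario_preset,
                       c(list(name = config$preset), config$sim))
    survey <- simulate_survey(sim_cfg, seed = config$seed)
    write_survey(survey, file.path(config$out_dir, "survey.csv"))
  } else {
    say("Reading survey from %s.", config$input)
    survey <- read_survey(config$input)
  }
  survey <- validate_survey(survey)
  full_months <- sort(unique(survey$month))
  for (s in sort(unique(survey$site))) {
    miss <- setdiff(full_months, survey$month[survey$site == s])
    if (length(miss) > 0) {
      say("Site %s is missing survey months %s; models use the remaining occasions.",
          s, paste(miss, collapse = ", "))
    }
  }

  say("Computing alpha diversity (%d plot-occasions).",
      nrow(distinct(survey, .data$site, .data$plot, .data$month)))
  alpha <- alpha_table(survey, transformed = config$transformed)
  readr::write_csv(alpha, file.path(config$out_dir, "alpha_diversity.csv"))

  say("Computing multiple-site beta diversity with jackknife uncertainty.")
  beta <- beta_summaries(survey, transformed = config$transformed,
                         jackknife = TRUE, ci_level = config$ci_level)
  readr::write_csv(beta, file.path(config$out_dir, "beta_diversity.csv"))

  say("Fitting treatment-by-time models.")
  fits <- fit_trend_models(survey, alpha = alpha, beta = beta,
                           alpha_metrics = config$alpha_metrics,
                           beta_components = config$beta_components,
                           transformed = config$transformed,
                           ci_level = config$ci_level)
  fits <- component_gating(fits)
  fit_rows <- purrr::map2(fits$fit, fits$interpretable, function(f, flag) {
    mutate(tidy(f), model_type = f$model_type, converged = f$converged,
           interpretable = flag)
  }) |> dplyr::bind_rows()
  readr::write_csv(fit_rows, file.path(config$out_dir, "model_fits.csv"))

  resid_rows <- purrr::map(fits$fit, function(f) {
    tibble(site = f$site, family = f$family, metric = f$metric,
           obs = seq_along(f$residuals), residual = f$residuals)
  }) |> dplyr::bind_rows()
  readr::write_csv(resid_rows, file.path(config$out_dir, "residuals.csv"))

  say("Computing pairwise cross-site contrasts.")
  metrics <- intersect(c(config$alpha_metrics, config$beta_components),
                       unique(fits$metric))
  contrasts <- purrr::map(metrics, function(m) {
    tryCatch(pairwise_contrasts(fits, metric = m,
                                ci_level = config$ci_level),
             exclodiv_contrast_error = function(e) {
               say("No contrasts for metric %s: %s", m, conditionMessage(e))
               NULL
             })
  }) |> dplyr::bind_rows()
  readr::write_csv(contrasts, file.path(config$out_dir, "contrasts.csv"))

  manifest <- list(
    config = config[setdiff(names(config), "sim")],
    sim_overrides = config$sim,
    seed = config$seed,
    versions = list(exclodiv = as.character(packageVersion("exclodiv")),
                    R = as.character(getRversion())),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (config$verbose || length(log_lines) > 0) {
    writeLines(log_lines, log_path)
  }
  say("Done; outputs in %s.", config$out_dir)

  invisible(list(survey = survey, alpha = alpha, beta = beta, fits = fits,
                 model_fits = fit_rows, residuals = resid_rows,
                 contrasts = contrasts, out_dir = config$out_dir))
}
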