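#' Configuration for the synthetic exclosure-survey generator
#'
#' Builds the parameter set consumed by [simulate_survey()]. Defaults emulate
#' the design of a long-running paired mammal-exclosure experiment: four
#' forest sites, 15 plot pairs per site (one fenced exclusion plot and one
#' open control plot), 18 survey occasions spanning 13 years (6-monthly at
#' first, then annual), site species pools of 170-229 taxa, and a small set
#' of hyperdominant taxa (palm/bamboo/fern analogues) that are released when
#' mammals are excluded. One site carries missing survey occasions so the
#' downstream pipeline must tolerate unbalanced designs.
#'
#' The generative model (see `vignette("exclodiv-methods")`) makes
#' `delta_richness` the expected per-month treatment-by-time interaction on
#' plot richness, `hyper_release_rate` a per-month log-abundance increase of
#' hyperdominant taxa under exclusion, and `convergence_rate` a geometric
#' per-month shrinkage of exclusion-plot compositional idiosyncrasies toward
#' the site mean (the homogenization mechanism).
#'
#' @param n_sites Number of forest sites.
#' @param sites Site labels; length `n_sites`.
#' @param n_pairs Plot pairs per site (each pair = 1 control + 1 exclusion).
#' @param months Ordered integer survey months (0-origin per site).
#' @param missing_months_by_site Named list mapping a site label to survey
#'   months absent for that site (dropped after generation).
#' @param pool_size Species-pool size per site; recycled to `n_sites`.
#' @param n_hyperdominant Number of hyperdominant taxa per site (the most
#'   common taxa of the pool).
#' @param sad_meanlog,sad_sdlog Log-normal species-abundance-distribution
#'   parameters for site-level species commonness.
#' @param richness0 Baseline expected per-plot richness at month 0.
#' @param pair_sd SD of pair-level richness offsets (the random intercept the
#'   alpha models estimate), in species units.
#' @param beta_time_richness Per-month expected richness trend in control
#'   plots (species/month).
#' @param delta_richness Additional per-month richness trend in exclusion
#'   plots (species/month); the true alpha interaction effect.
#' @param hyper_release_rate Per-month increase in log abundance (and log
#'   selection weight) of hyperdominant taxa under exclusion.
#' @param affinity_sd SD of persistent plot-by-species log-affinities;
#'   controls baseline beta diversity among plots.
#' @param convergence_rate Per-month geometric shrinkage of exclusion-plot
#'   affinities toward the site mean, in `[0, 1]`; 0 disables homogenization.
#' @param count_scale Baseline scale of conditional expected counts per
#'   present species.
#' @param dispersion Negative-binomial size parameter for count noise;
#'   `Inf` gives Poisson counts.
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   surveys.
#'
#' @return An object of class `exclo_sim_config` (a validated named list).
#' @seealso [scenario_preset()], [simulate_survey()]
#' @examples
#' cfg <- sim_config(n_sites = 1, n_pairs = 5, months = seq(0, 42, by = 6),
#'                   pool_size = 30, richness0 = 10)
#' cfg$delta_richness
#' @export
sim_config <- function(n_sites = 4,
                       sites = c("ITA", "CAR", "CBO", "VG")[seq_len(n_sites)],
                       n_pairs = 15,
                       months = c(seq(0, 90, by = 6), 108, 156),
                       missing_months_by_site = list(CBO = c(54, 60, 66, 156)),
                       pool_size = c(170, 183, 186, 229)[seq_len(min(n_sites, 4))],
                       n_hyperdominant = 3,
                       sad_meanlog = 0,
                       sad_sdlog = 1.5,
                       richness0 = 25,
                       pair_sd = 2,
                       beta_time_richness = 0.03,
                       delta_richness = 0.05,
                       hyper_release_rate = 0.01,
                       affinity_sd = 1,
                       convergence_rate = 0.015,
                       count_scale = 2,
                       dispersion = 5,
                       seed = 1L) {
  check_number(n_sites, "n_sites", min = 1, integer = TRUE)
  if (!is.character(sites) || length(sites) != n_sites || anyDuplicated(sites)) {
    abort("Invalid configuration field `sites`: need `n_sites` distinct labels.",
          class = "exclodiv_config_error")
  }
  check_number(n_pairs, "n_pairs", min = 1, integer = TRUE)
  if (!is.numeric(months) || length(months) < 1 || any(months < 0) ||
      any(months != round(months)) || is.unsorted(months, strictly = TRUE)) {
    abort("Invalid configuration field `months`: need strictly increasing non-negative integers.",
          class = "exclodiv_config_error")
  }
  if (missing(missing_months_by_site)) {
    # default pattern only applies to the sites actually simulated
    missing_months_by_site <-
      missing_months_by_site[names(missing_months_by_site) %in% sites]
  }
  if (!is.list(missing_months_by_site) ||
      (length(missing_months_by_site) > 0 &&
       (is.null(names(missing_months_by_site)) ||
        !all(names(missing_months_by_site) %in% sites)))) {
    abort("Invalid configuration field `missing_months_by_site`: must be a named list keyed by site label.",
          class = "exclodiv_config_error")
  }
  pool_size <- rep_len(as.integer(pool_size), n_sites)
  if (any(pool_size < 1)) {
    abort("Invalid configuration field `pool_size`: all pools must be >= 1.",
          class = "exclodiv_config_error")
  }
  check_number(n_hyperdominant, "n_hyperdominant", min = 0, integer = TRUE)
  if (n_hyperdominant > min(pool_size)) {
    abort("Invalid configuration field `n_hyperdominant`: cannot exceed `pool_size`.",
          class = "exclodiv_config_error")
  }
  check_number(sad_meanlog, "sad_meanlog")
  check_number(sad_sdlog, "sad_sdlog", min = 0)
  check_number(richness0, "richness0", min = 1)
  check_number(pair_sd, "pair_sd", min = 0)
  check_number(beta_time_richness, "beta_time_richness")
  check_number(delta_richness, "delta_richness")
  check_number(hyper_release_rate, "hyper_release_rate")
  check_number(affinity_sd, "affinity_sd", min = 0)
  check_number(convergence_rate, "convergence_rate", min = 0, max = 1)
  check_number(count_scale, "count_scale", min = 0)
  check_number(dispersion, "dispersion", min = 1e-8, allow_inf = TRUE)
  if (dispersion <= 0) {
    abort("Invalid configuration field `dispersion`: must be > 0.",
          class = "exclodiv_config_error")
  }
  check_number(seed, "seed", integer = TRUE)

  structure(
    list(n_sites = as.integer(n_sites), sites = sites,
         n_pairs = as.integer(n_pairs), months = as.integer(months),
         missing_months_by_site = missing_months_by_site,
         pool_size = pool_size, n_hyperdominant = as.integer(n_hyperdominant),
         sad_meanlog = sad_meanlog, sad_sdlog = sad_sdlog,
         richness0 = richness0, pair_sd = pair_sd,
         beta_time_richness = beta_time_richness,
         delta_richness = delta_richness,
         hyper_release_rate = hyper_release_rate,
         affinity_sd = affinity_sd, convergence_rate = convergence_rate,
         count_scale = count_scale, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "exclo_sim_config"
  )
}

#' @export
print.exclo_sim_config <- function(x, ...) {
  cat("<exclo_sim_config>\n")
  cat(sprintf("  sites: %s (pools %s)\n", paste(x$sites, collapse = ", "),
              paste(x$pool_size, collapse = "/")))
  cat(sprintf("  %d pairs x 2 treatments, %d survey months (max %d)\n",
              x$n_pairs, length(x$months), max(x$months)))
  cat(sprintf("  effects: delta_richness=%g, hyper_release_rate=%g, convergence_rate=%g\n",
              x$delta_richness, x$hyper_release_rate, x$convergence_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Ready-made simulation scenarios
#'
#' Named presets for [sim_config()]:
#' * `"null"` — no treatment effect of any kind (`delta_richness`,
#'   `hyper_release_rate` and `convergence_rate` all 0); used for type-I
#'   error calibration.
#' * `"homogenization"` — the headline scenario: richness rises faster under
#'   exclusion, hyperdominant taxa are released, and exclusion-plot
#'   compositions converge so beta diversity declines.
#' * `"release_only"` — hyperdominant release without richness or
#'   convergence effects.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return An `exclo_sim_config`.
#' @examples
#' scenario_preset("null")$convergence_rate
#' @export
scenario_preset <- function(name, ...) {
  presets <- c("null", "homogenization", "release_only")
  if (missing(name) || length(name) != 1 || !is.character(name) ||
      !name %in% presets) {
    abort(sprintf("Unknown scenario preset. Available presets: %s.",
                  paste(presets, collapse = ", ")),
          class = "exclodiv_config_error")
  }
  base <- switch(name,
    null = list(delta_richness = 0, hyper_release_rate = 0,
                convergence_rate = 0),
    homogenization = list(),
    release_only = list(delta_richness = 0, hyper_release_rate = 0.01,
                        convergence_rate = 0)
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}
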