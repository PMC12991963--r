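#' Simulate a paired-exclosure community survey
#'
#' Generates a long-format survey table with the statistical structure the
#' downstream analysis assumes. The generative model, per site:
#'
#' 1. Species commonness: per-species log-abundance `sad_s ~ N(sad_meanlog,
#'    sad_sdlog^2)`; the `n_hyperdominant` most common taxa are flagged
#'    hyperdominant.
#' 2. Plot structure: pair-level richness offsets `b_pair ~ N(0, pair_sd^2)`
#'    shared by both plots of a pair; persistent plot-by-species
#'    log-affinities `a_ps ~ N(0, affinity_sd^2)` differentiate plots.
#' 3. Occupancy: at month `t` the expected plot richness is
#'    `m = richness0 + b_pair + (beta_time_richness + excl * delta_richness) * t`
#'    (clamped to `[1, pool]`); the realised species number is
#'    `Binomial(pool, m / pool)`, so expected richness is exactly linear in
#'    month with interaction slope `delta_richness`.
#' 4. Composition: the present species are a weighted sample without
#'    replacement with log-weights
#'    `sad_s + a_ps * shrink(t) + excl * t * hyper_release_rate * hyper_s`,
#'    where `shrink(t) = (1 - convergence_rate)^t` for exclusion plots and 1
#'    for controls — exclusion-plot idiosyncrasies decay geometrically, the
#'    homogenization mechanism.
#' 5. Counts: each present species gets `1 + NB(mu, size = dispersion)`
#'    individuals (Poisson when `dispersion = Inf`) with
#'    `mu = count_scale * exp(log-weight - sad_meanlog)`, summed over the
#'    sampled subplots of the plot.
#'
#' Site-specific missing survey months are dropped after generation, so the
#' pipeline must tolerate unbalanced designs.
#'
#' @param config An [sim_config()] / [scenario_preset()] object.
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   `(config, seed)` yields an identical table.
#' @return A tibble with columns `site`, `pair`, `plot`, `treatment`
#'   (`"control"`/`"exclusion"`), `month`, `species`, `count`; one row per
#'   species observed in a plot at a survey occasion (counts >= 1).
#' @examples
#' survey <- simulate_survey(sim_config(n_sites = 1, n_pairs = 3,
#'                                      months = c(0, 6, 12), pool_size = 40,
#'                                      richness0 = 12), seed = 7)
#' dplyr::count(survey, treatment)
#' @export
simulate_survey <- function(config = scenario_preset("homogenization"),
                            seed = NULL) {
  if (!inherits(config, "exclo_sim_config")) {
    abort("`config` must be an `exclo_sim_config` (see `sim_config()`).",
          class = "exclodiv_config_error")
  }
  seed <- seed %||% config$seed
  withr::local_seed(seed)
  out <- purrr::map(seq_len(config$n_sites), function(i) {
    simulate_site(config, config$sites[i], config$pool_size[i])
  })
  dplyr::bind_rows(out)
}

simulate_site <- function(cfg, site, pool) {
  sp_ids <- sprintf("sp%03d", seq_len(pool))
  sad <- rnorm(pool, cfg$sad_meanlog, cfg$sad_sdlog)
  hyper <- logical(pool)
  hyper[order(sad, decreasing = TRUE)[seq_len(cfg$n_hyperdominant)]] <- TRUE

  months <- setdiff(cfg$months, cfg$missing_months_by_site[[site]])
  pairs <- sprintf("P%02d", seq_len(cfg$n_pairs))
  b_pair <- rnorm(cfg$n_pairs, 0, cfg$pair_sd)

  n_plots <- 2L * cfg$n_pairs
  plot_pair <- rep(seq_len(cfg$n_pairs), each = 2L)
  plot_trt <- rep(treatment_levels, times = cfg$n_pairs)
  plot_ids <- paste0(pairs[plot_pair], ifelse(plot_trt == "control", "C", "E"))
  affinity <- matrix(rnorm(n_plots * pool, 0, cfg$affinity_sd),
                     nrow = n_plots)

  release <- cfg$hyper_release_rate * hyper
  acc <- vector("list", n_plots * length(months))
  k <- 0L
  for (p in seq_len(n_plots)) {
    excl <- plot_trt[p] == "exclusion"
    for (t in months) {
      shrink <- if (excl) (1 - cfg$convergence_rate)^t else 1
      m <- cfg$richness0 + b_pair[plot_pair[p]] +
        (cfg$beta_time_richness + (if (excl) cfg$delta_richness else 0)) * t
      m <- min(max(m, 1), pool)
      n_present <- max(rbinom(1L, pool, m / pool), 1L)
      logw <- sad + affinity[p, ] * shrink + (if (excl) release * t else 0)
      idx <- sample.int(pool, n_present, prob = exp(logw - max(logw)))
      mu <- cfg$count_scale * exp(logw[idx] - cfg$sad_meanlog)
      extra <- if (is.infinite(cfg$dispersion)) {
        rpois(n_present, mu)
      } else {
        rnbinom(n_present, mu = mu, size = cfg$dispersion)
      }
      k <- k + 1L
      acc[[k]] <- list(p = p, t = t, idx = sort(idx),
                       count = (1L + extra)[order(idx)])
    }
  }

  lens <- vapply(acc, function(a) length(a$idx), integer(1))
  p_all <- rep(vapply(acc, `[[`, integer(1), "p"), lens)
  tibble(
    site = site,
    pair = pairs[plot_pair[p_all]],
    plot = plot_ids[p_all],
    treatment = plot_trt[p_all],
    month = rep(vapply(acc, `[[`, integer(1), "t"), lens),
    species = sp_ids[unlist(lapply(acc, `[[`, "idx"))],
    count = as.integer(unlist(lapply(acc, `[[`, "count")))
  )
}
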