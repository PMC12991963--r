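#' Treatment-by-time model for a plot-level alpha diversity metric
#'
#' Fits, for one site, the linear mixed-effects model
#' `metric ~ beta0 + beta1 * month + beta2 * exclusion +
#' beta3 * month * exclusion + b_pair`, with a pair-level random intercept
#' `b_pair ~ N(0, sigma2_pairs)` absorbing the paired design. Control is the
#' baseline treatment, month is a continuous covariate in raw survey months
#' (0-origin), and `beta3` — the treatment-by-time interaction — is the
#' effect size of interest: the difference in per-month trend between
#' exclusion and control plots. Estimation is REML via [lme4::lmer()] with
#' Wald normal-approximation standard errors, confidence intervals and
#' p-values.
#'
#' @param records An alpha table (see [alpha_table()]) for a single site.
#' @param metric Response column: `"richness"`, `"shannon"` or
#'   `"inv_simpson"`.
#' @param ci_level Confidence level for Wald intervals.
#' @return An `exclo_fit` object; see [tidy.exclo_fit()] / [glance.exclo_fit()].
#' @examples
#' survey <- simulate_survey(sim_config(n_sites = 1, n_pairs = 5,
#'   months = seq(0, 42, 6), pool_size = 30, richness0 = 10))
#' fit <- fit_alpha_model(alpha_table(survey), metric = "richness")
#' tidy(fit)
#' @export
fit_alpha_model <- function(records, metric = c("richness", "shannon",
                                                "inv_simpson"),
                            ci_level = 0.95) {
  metric <- match.arg(metric)
  site <- unique(records$site)
  if (length(site) != 1) {
    abort("`records` must cover exactly one site; fit sites separately.",
          class = "exclodiv_model_error")
  }
  dat <- tibble(
    y = records[[metric]],
    month = as.numeric(records$month),
    treatment = as_treatment(records$treatment),
    pair = factor(records$pair)
  )
  n_drop <- sum(!is.finite(dat$y))
  if (n_drop > 0) {
    inform(sprintf("Dropping %d record(s) with missing %s (degenerate plots) at site %s.",
                   n_drop, metric, site))
    dat <- dat[is.finite(dat$y), , drop = FALSE]
  }
  if (nlevels(droplevels(dat$pair)) < 2 || length(unique(dat$month)) < 2) {
    abort(sprintf("Need >= 2 pairs and >= 2 distinct months at site %s.", site),
          class = "exclodiv_model_error")
  }

  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(y ~ month * treatment + (1 | pair), data = dat, REML = TRUE),
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    },
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  # boundary (singular) fits are usable estimates, tracked separately from
  # genuine optimizer failures
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- !any(!grepl("boundary \\(singular\\)", conv_msgs))
  singular <- lme4::isSingular(fit)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm((1 + ci_level) / 2)
  coefs <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se), conf.high = unname(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_exclo_fit(
    site = site, metric = metric, family = "alpha", model_type = "lmm",
    coefficients = coefs,
    sigma2_pairs = vc$vcov[vc$grp == "pair"][1],
    sigma2_resid = vc$vcov[vc$grp == "Residual"][1],
    n_obs = nrow(dat), converged = converged, singular = singular,
    ci_level = ci_level, residuals = unname(resid(fit)), model = fit
  )
}

#' Treatment-by-time model for a multiple-site beta diversity component
#'
#' Fits, for one site, the ordinary least-squares model
#' `component ~ month * treatment` on the treatment-level multiple-site
#' summaries (one value per treatment and occasion, so no random effect and
#' no weighting by default). Inference is the standard OLS t-based output.
#'
#' @param summaries A [beta_summaries()] tibble for a single site.
#' @param component `"total"`, `"balanced"` or `"gradient"`.
#' @param ci_level Confidence level.
#' @param weights Optional `"jackknife"` to weight observations by
#'   `1 / se_component^2` (off by default; the plain fit matches common
#'   practice on such summaries).
#' @return An `exclo_fit` object.
#' @export
fit_beta_model <- function(summaries, component = c("total", "balanced",
                                                    "gradient"),
                           ci_level = 0.95, weights = c("none", "jackknife")) {
  component <- match.arg(component)
  weights <- match.arg(weights)
  site <- unique(summaries$site)
  if (length(site) != 1) {
    abort("`summaries` must cover exactly one site; fit sites separately.",
          class = "exclodiv_model_error")
  }
  dat <- summaries
  if ("ok" %in% names(dat)) {
    n_bad <- sum(!dat$ok)
    if (n_bad > 0) {
      inform(sprintf("Dropping %d flagged missing summar%s at site %s.",
                     n_bad, if (n_bad == 1) "y" else "ies", site))
      dat <- dat[dat$ok, , drop = FALSE]
    }
  }
  dat <- tibble(
    y = dat[[component]],
    month = as.numeric(dat$month),
    treatment = as_treatment(dat$treatment),
    w = if (weights == "jackknife") 1 / dat[[paste0("se_", component)]]^2 else 1
  )
  occ <- table(dat$treatment)
  if (any(occ < 3)) {
    abort(sprintf("Need >= 3 occasions per treatment at site %s (have %s).",
                  site, paste(occ, collapse = "/")),
          class = "exclodiv_model_error")
  }
  fit <- lm(y ~ month * treatment, data = dat, weights = w)
  # suppress only the benign "essentially perfect fit" warning on exact data
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, level = ci_level))
  coefs <- tibble(
    term = rownames(sm$coefficients),
    estimate = as.numeric(sm$coefficients[, "Estimate"]),
    std.error = as.numeric(sm$coefficients[, "Std. Error"]),
    statistic = as.numeric(sm$coefficients[, "t value"]),
    p.value = as.numeric(sm$coefficients[, "Pr(>|t|)"]),
    conf.low = as.numeric(ci[, 1]), conf.high = as.numeric(ci[, 2])
  )
  new_exclo_fit(
    site = site, metric = component, family = "beta", model_type = "ols",
    coefficients = coefs, sigma2_pairs = NA_real_,
    sigma2_resid = sm$sigma^2, n_obs = nrow(dat), converged = TRUE,
    singular = FALSE, ci_level = ci_level, residuals = unname(resid(fit)),
    model = fit
  )
}

new_exclo_fit <- function(site, metric, family, model_type, coefficients,
                          sigma2_pairs, sigma2_resid, n_obs, converged,
                          singular, ci_level, residuals, model) {
  structure(
    list(site = site, metric = metric, family = family,
         model_type = model_type, coefficients = coefficients,
         sigma2_pairs = sigma2_pairs, sigma2_resid = sigma2_resid,
         n_obs = n_obs, converged = converged, singular = singular,
         ci_level = ci_level, residuals = residuals, model = model),
    class = "exclo_fit"
  )
}

interaction_term <- "month:treatmentexclusion"

#' @export
print.exclo_fit <- function(x, ...) {
  cat(sprintf("<exclo_fit> %s model: %s ~ month * treatment%s  (site %s, n = %d%s)\n",
              x$model_type, x$metric,
              if (x$model_type == "lmm") " + (1 | pair)" else "",
              x$site, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  print(x$coefficients)
  invisible(x)
}

#' Broom-style accessors for treatment-by-time fits
#'
#' `tidy()` returns the coefficient table (term, estimate, std.error,
#' statistic, p.value, conf.low, conf.high); `glance()` returns a one-row
#' model summary including the interaction p-value.
#'
#' @param x An `exclo_fit`.
#' @param ... Unused.
#' @export
tidy.exclo_fit <- function(x, ...) {
  mutate(x$coefficients, site = x$site, metric = x$metric,
         family = x$family, .before = 1)
}

#' @rdname tidy.exclo_fit
#' @export
glance.exclo_fit <- function(x, ...) {
  i <- match(interaction_term, x$coefficients$term)
  tibble(site = x$site, family = x$family, metric = x$metric,
         model_type = x$model_type, n_obs = x$n_obs,
         sigma2_pairs = x$sigma2_pairs, sigma2_resid = x$sigma2_resid,
         estimate_interaction = x$coefficients$estimate[i],
         p_interaction = x$coefficients$p.value[i],
         converged = x$converged, singular = x$singular)
}

#' Fit all treatment-by-time models for a survey
#'
#' Convenience wrapper: computes the alpha table and beta summaries (unless
#' supplied) and fits one model per site x metric — mixed models for the
#' alpha metrics, linear models for the beta components. Sites failing to
#' fit are reported and skipped rather than aborting the run.
#'
#' @param survey A survey tibble.
#' @param alpha,beta Optional precomputed [alpha_table()] /
#'   [beta_summaries()] outputs.
#' @param alpha_metrics,beta_components Metrics to fit.
#' @param transformed Passed to the table builders.
#' @param ci_level Confidence level.
#' @return A tibble with one row per site x metric: glance columns plus a
#'   `fit` list-column of `exclo_fit` objects.
#' @export
fit_trend_models <- function(survey, alpha = NULL, beta = NULL,
                             alpha_metrics = c("richness", "shannon",
                                               "inv_simpson"),
                             beta_components = c("total", "balanced",
                                                 "gradient"),
                             transformed = TRUE, ci_level = 0.95) {
  alpha <- alpha %||% alpha_table(survey, transformed = transformed)
  beta <- beta %||% beta_summaries(survey, transformed = transformed,
                                   jackknife = FALSE)
  grid <- dplyr::bind_rows(
    expand_grid(site = sort(unique(alpha$site)), family = "alpha",
                metric = alpha_metrics),
    expand_grid(site = sort(unique(beta$site)), family = "beta",
                metric = beta_components)
  )
  fits <- purrr::pmap(grid, function(site, family, metric) {
    tryCatch({
      if (family == "alpha") {
        fit_alpha_model(alpha[alpha$site == site, , drop = FALSE],
                        metric = metric, ci_level = ci_level)
      } else {
        fit_beta_model(beta[beta$site == site, , drop = FALSE],
                       component = metric, ci_level = ci_level)
      }
    }, exclodiv_model_error = function(e) {
      warn(sprintf("Skipping %s/%s at site %s: %s",
                   family, metric, site, conditionMessage(e)))
      NULL
    })
  })
  keep <- !vapply(fits, is.null, logical(1))
  out <- purrr::map(fits[keep], glance) |> dplyr::bind_rows()
  out$fit <- fits[keep]
  out
}

#' Gate beta components on the total-dissimilarity interaction
#'
#' Balanced-variation and abundance-gradient fits are flagged interpretable
#' only when the corresponding total beta diversity model shows a
#' significant treatment-by-time interaction (`p < alpha_level`, strict
#' inequality — a boundary p-value exactly at the threshold is
#' non-interpretable). Components are still reported either way; the flag
#' records the interpretation rule.
#'
#' @param fits A [fit_trend_models()] tibble (needs `site`, `family`,
#'   `metric`, `p_interaction`).
#' @param alpha_level Significance threshold (default 0.05).
#' @return `fits` with an added `interpretable` column: `TRUE`/`FALSE` for
#'   beta components, `TRUE` for total and all alpha metrics.
#' @export
component_gating <- function(fits, alpha_level = 0.05) {
  beta_sites <- unique(fits$site[fits$family == "beta"])
  totals <- fits |> filter(.data$family == "beta", .data$metric == "total")
  missing_total <- setdiff(beta_sites, totals$site)
  if (length(missing_total) > 0) {
    abort(sprintf("No total beta diversity fit for site(s) %s; cannot gate components.",
                  paste(missing_total, collapse = ", ")),
          class = "exclodiv_model_error")
  }
  gate <- setNames(totals$p_interaction < alpha_level, totals$site)
  mutate(fits, interpretable = dplyr::case_when(
    .data$family != "beta" ~ TRUE,
    .data$metric == "total" ~ TRUE,
    TRUE ~ unname(gate[.data$site])
  ))
}
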