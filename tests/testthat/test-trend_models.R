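# deterministic alpha records lying exactly on the model surface
exact_alpha_records <- function(beta = c(10, 0.05, -1, 0.04),
                                pair_offsets = seq(-2, 2, length.out = 5),
                                months = seq(0, 42, by = 6),
                                metric = "richness") {
  grid <- tidyr::expand_grid(pair = sprintf("P%d", seq_along(pair_offsets)),
                             treatment = c("control", "exclusion"),
                             month = months)
  grid$site <- "S1"
  grid$plot <- paste0(grid$pair, substr(grid$treatment, 1, 1))
  excl <- as.numeric(grid$treatment == "exclusion")
  grid[[metric]] <- beta[1] + beta[2] * grid$month + beta[3] * excl +
    beta[4] * grid$month * excl +
    pair_offsets[match(grid$pair, unique(grid$pair))]
  grid
}

test_that("noiseless alpha data recover the generating coefficients", {
  rec <- exact_alpha_records(pair_offsets = rep(0, 5))
  fit <- fit_alpha_model(rec, metric = "richness")
  est <- tidy(fit)$estimate
  expect_equal(est, c(10, 0.05, -1, 0.04), tolerance = 1e-6)
  expect_equal(fit$sigma2_resid, 0, tolerance = 1e-8)
})

test_that("pair offsets are absorbed by the random intercept (GLS = OLS)", {
  # in a balanced paired design the mixed-model fixed effects coincide with
  # the OLS fit whatever the pair-level variance
  set.seed(400)
  rec <- exact_alpha_records()
  rec$richness <- rec$richness + rnorm(nrow(rec), 0, 0.5)
  fit <- fit_alpha_model(rec, "richness")
  ols <- lm(richness ~ month * treatment,
            data = dplyr::mutate(rec, treatment = factor(treatment)))
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_gt(fit$sigma2_pairs, 0)
})

test_that("swapping the treatment coding flips beta2 and beta3", {
  set.seed(403)
  rec <- exact_alpha_records()
  rec$richness <- rec$richness + rnorm(nrow(rec), 0, 0.5)
  swapped <- dplyr::mutate(rec, treatment = ifelse(treatment == "control",
                                                  "exclusion", "control"))
  est <- tidy(fit_alpha_model(rec, "richness"))$estimate
  est_sw <- tidy(fit_alpha_model(swapped, "richness"))$estimate
  expect_equal(est_sw[3:4], -est[3:4], tolerance = 1e-6)
  expect_equal(est_sw[1:2], est[1:2] + est[3:4], tolerance = 1e-6)
})

test_that("with no pair-level variance the mixed fixed effects match OLS", {
  set.seed(401)
  rec <- exact_alpha_records(pair_offsets = rep(0, 6))
  rec$richness <- rec$richness + rnorm(nrow(rec), 0, 0.5)
  fit <- fit_alpha_model(rec, "richness")
  ols <- lm(richness ~ month * treatment,
            data = dplyr::mutate(rec, treatment = factor(treatment)))
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("shifting all months changes intercept terms, not the slopes", {
  set.seed(402)
  rec <- exact_alpha_records()
  rec$richness <- rec$richness + rnorm(nrow(rec), 0, 0.3)
  fit0 <- tidy(fit_alpha_model(rec, "richness"))$estimate
  rec12 <- dplyr::mutate(rec, month = month + 12)
  fit12 <- tidy(fit_alpha_model(rec12, "richness"))$estimate
  expect_equal(fit12[c(2, 4)], fit0[c(2, 4)], tolerance = 1e-6)
  expect_equal(fit12[1], fit0[1] - 12 * fit0[2], tolerance = 1e-5)
})

test_that("mixed-model residuals average out and pair variance is reported", {
  cfg <- small_null_cfg()
  survey <- simulate_survey(cfg, seed = 41)
  fit <- fit_alpha_model(alpha_table(survey), "richness")
  expect_lt(abs(mean(fit$residuals)), 0.05)
  expect_gte(fit$sigma2_pairs, 0)
  expect_gt(fit$sigma2_resid, 0)
  expect_equal(fit$n_obs, 80L)
})

test_that("beta summaries lying exactly on two lines are fit exactly", {
  months <- seq(0, 60, by = 6)
  summaries <- dplyr::bind_rows(
    tibble::tibble(site = "S1", month = months, treatment = "control",
                   total = 0.5 + 0.001 * months),
    tibble::tibble(site = "S1", month = months, treatment = "exclusion",
                   total = 0.55 - 0.002 * months)
  )
  fit <- fit_beta_model(summaries, "total")
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "month:treatmentexclusion"], -0.003,
               tolerance = 1e-10)
  # identical series in both treatments: no treatment terms
  same <- dplyr::mutate(summaries, total = 0.5 + 0.001 * month)
  est2 <- tidy(fit_beta_model(same, "total"))
  expect_equal(est2$estimate[3:4], c(0, 0), tolerance = 1e-12)
  # OLS residuals sum to zero exactly
  expect_equal(sum(fit_beta_model(same, "total")$residuals), 0,
               tolerance = 1e-10)
})

test_that("beta models refuse fewer than three occasions per treatment", {
  summaries <- tibble::tibble(
    site = "S1", month = rep(c(0, 6), 2),
    treatment = rep(c("control", "exclusion"), each = 2),
    total = c(0.5, 0.52, 0.48, 0.47))
  expect_error(fit_beta_model(summaries, "total"), "occasions",
               class = "exclodiv_model_error")
})

test_that("fit_trend_models fits every site-by-metric combination", {
  cfg <- sim_config(n_sites = 2, n_pairs = 4, months = seq(0, 18, 6),
                    pool_size = 30, richness0 = 10,
                    missing_months_by_site = list())
  survey <- simulate_survey(cfg, seed = 43)
  fits <- fit_trend_models(survey)
  expect_equal(nrow(fits), 2 * 6)
  expect_setequal(unique(fits$metric),
                  c("richness", "shannon", "inv_simpson",
                    "total", "balanced", "gradient"))
  expect_true(all(vapply(fits$fit, inherits, logical(1), "exclo_fit")))
  expect_true(all(is.finite(fits$p_interaction)))
})

test_that("component gating applies the strict significance rule", {
  fake <- tibble::tibble(
    site = rep("S1", 4),
    family = c("alpha", "beta", "beta", "beta"),
    metric = c("richness", "total", "balanced", "gradient"),
    p_interaction = c(0.5, 0.20, 0.001, 0.001))
  gated <- component_gating(fake)
  expect_false(any(gated$interpretable[gated$metric %in%
                                         c("balanced", "gradient")]))
  fake$p_interaction[2] <- 0.01
  gated <- component_gating(fake)
  expect_true(all(gated$interpretable))
  # boundary p exactly at the threshold is non-interpretable
  fake$p_interaction[2] <- 0.05
  gated <- component_gating(fake)
  expect_false(gated$interpretable[3])
  expect_true(gated$interpretable[gated$metric == "total"])
  expect_error(component_gating(fake[fake$metric != "total", ]),
               class = "exclodiv_model_error")
})
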