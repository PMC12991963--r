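test_that("se_from_ci inverts the symmetric normal interval", {
  expect_equal(se_from_ci(-0.1, 0.3), 0.4 / (2 * qnorm(0.975)),
               tolerance = 1e-9)
  expect_equal(se_from_ci(-0.1, 0.3), 0.102042, tolerance = 1e-5)
  expect_equal(se_from_ci(0, 1, level = 0.90), 1 / (2 * qnorm(0.95)),
               tolerance = 1e-12)
  expect_equal(se_from_ci(0, 1, level = 0.90), 0.303980, tolerance = 1e-5)
  # exact round-trip for any estimate/se
  set.seed(501)
  for (i in 1:20) {
    est <- rnorm(1); s <- rexp(1); lvl <- runif(1, 0.5, 0.99)
    z <- qnorm((1 + lvl) / 2)
    expect_equal(se_from_ci(est - z * s, est + z * s, level = lvl), s,
                 tolerance = 1e-9)
  }
  expect_error(se_from_ci(1, 1), class = "exclodiv_contrast_error")
  expect_error(se_from_ci(0, 1, level = 1.2),
               class = "exclodiv_contrast_error")
})

fake_interactions <- function(est, se, sites = NULL, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  sites <- if (is.null(sites)) names(est) else sites
  est <- unname(est)
  se <- unname(se)
  tibble::tibble(site = sites, metric = "richness", estimate = est,
                 std.error = se, conf.low = est - z * se,
                 conf.high = est + z * se, converged = TRUE)
}

test_that("pairwise contrasts follow standard-normal z-test algebra", {
  tab <- fake_interactions(c(A = 0.3, B = 0.1),
                           se = c(0.1, 0) + c(0.06, 0.08))
  ct <- pairwise_contrasts(tab, "richness")
  expect_equal(ct$diff, 0.2, tolerance = 1e-12)
  expect_equal(ct$se_diff, sqrt(0.16^2 + 0.08^2), tolerance = 1e-9)

  # forced diff = 0.2, se_diff = 0.1 -> z = 2, p = 2 * (1 - pnorm(2))
  tab2 <- fake_interactions(c(A = 0.2, B = 0), se = c(0.1, 0.1) / sqrt(2))
  ct2 <- pairwise_contrasts(tab2, "richness")
  expect_equal(ct2$z, 2, tolerance = 1e-9)
  expect_equal(ct2$p, 2 * pnorm(-2), tolerance = 1e-9)
  expect_equal(ct2$p, 0.0455, tolerance = 1e-3)

  # identical estimates and intervals: no difference at all
  tab3 <- fake_interactions(c(A = 0.05, B = 0.05), se = c(0.02, 0.02))
  ct3 <- pairwise_contrasts(tab3, "richness")
  expect_equal(ct3$diff, 0)
  expect_equal(ct3$z, 0)
  expect_equal(ct3$p, 1)
})

test_that("four sites give six antisymmetric contrasts", {
  tab <- fake_interactions(c(ITA = 0.09, CAR = 0.055, CBO = 0.055,
                             VG = 0.05),
                           se = c(0.01, 0.012, 0.011, 0.013))
  ct <- pairwise_contrasts(tab, "richness")
  expect_equal(nrow(ct), 6)
  expect_setequal(paste(ct$site_x, ct$site_y),
                  c("ITA CAR", "ITA CBO", "ITA VG", "CAR CBO", "CAR VG",
                    "CBO VG"))
  # reversing the site order negates diff and z but preserves p
  rev_ct <- pairwise_contrasts(tab[4:1, ], "richness")
  key <- function(x) paste(pmin(x$site_x, x$site_y), pmax(x$site_x, x$site_y))
  m <- match(key(ct), key(rev_ct))
  expect_equal(rev_ct$diff[m], -ct$diff)
  expect_equal(rev_ct$z[m], -ct$z)
  expect_equal(rev_ct$p[m], ct$p, tolerance = 1e-12)
  expect_equal(rev_ct$ci_low[m], -ct$ci_high, tolerance = 1e-12)
})

test_that("CI-derived and Wald standard errors coincide for normal intervals", {
  cfg <- small_null_cfg()
  survey <- simulate_survey(cfg, seed = 51)
  fit <- fit_alpha_model(alpha_table(survey), "richness")
  row <- tidy(fit)[tidy(fit)$term == "month:treatmentexclusion", ]
  expect_equal(se_from_ci(row$conf.low, row$conf.high), row$std.error,
               tolerance = 1e-9)
})

test_that("contrasts skip non-converged fits and need two usable sites", {
  tab <- fake_interactions(c(A = 0.1, B = 0.2, C = 0.15),
                           se = c(0.02, 0.02, 0.02))
  tab$converged[3] <- FALSE
  expect_message(ct <- pairwise_contrasts(tab, "richness"),
                 "non-converged")
  expect_equal(nrow(ct), 1)
  tab$converged[2] <- FALSE
  expect_error(suppressMessages(pairwise_contrasts(tab, "richness")),
               class = "exclodiv_contrast_error")
})

test_that("contrasts extracted from real fits agree with manual extraction", {
  cfg <- sim_config(n_sites = 2, n_pairs = 4, months = seq(0, 18, 6),
                    pool_size = 30, richness0 = 10,
                    missing_months_by_site = list())
  survey <- simulate_survey(cfg, seed = 53)
  fits <- fit_trend_models(survey, beta_components = "total")
  ct <- pairwise_contrasts(fits, "richness")
  expect_equal(nrow(ct), 1)
  rich <- fits[fits$metric == "richness", ]
  ints <- setNames(rich$estimate_interaction, rich$site)
  expect_equal(ct$diff, unname(ints[ct$site_x] - ints[ct$site_y]),
               tolerance = 1e-12)
  ses <- vapply(rich$fit, function(f) {
    td <- tidy(f)
    td$std.error[td$term == "month:treatmentexclusion"]
  }, numeric(1))
  expect_equal(ct$se_diff, sqrt(sum(ses^2)), tolerance = 1e-9)
})
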