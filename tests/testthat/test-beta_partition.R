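test_that("pairwise partition matches hand-evaluated component sums", {
  # A = 1, B = 3, C = 1 -> total 4/6, balanced 1/2, gradient 1/6
  p <- pairwise_bray_partition(c(2, 0, 2), c(1, 1, 0))
  expect_equal(p$total, 4 / 6, tolerance = 1e-12)
  expect_equal(p$balanced, 1 / 2, tolerance = 1e-12)
  expect_equal(p$gradient, 4 / 6 - 1 / 2, tolerance = 1e-12)

  ident <- pairwise_bray_partition(c(3, 1, 4), c(3, 1, 4))
  expect_equal(unlist(ident), c(total = 0, balanced = 0, gradient = 0))

  disjoint <- pairwise_bray_partition(c(3, 0), c(0, 5))
  expect_equal(unlist(disjoint), c(total = 1, balanced = 1, gradient = 0))

  expect_error(pairwise_bray_partition(c(0, 0), c(0, 0)),
               class = "exclodiv_beta_error")
  expect_error(pairwise_bray_partition(c(1, 2), c(1, 2, 3)),
               class = "exclodiv_beta_error")
})

test_that("multisite partition reduces to the pairwise formula at two plots", {
  m <- rbind(p1 = c(2, 0, 2), p2 = c(1, 1, 0))
  ms <- multisite_bray_partition(m)
  pw <- pairwise_bray_partition(m[1, ], m[2, ])
  expect_identical(ms$total, pw$total)
  expect_identical(ms$balanced, pw$balanced)
  expect_identical(ms$gradient, pw$gradient)
  # identical plots carry no dissimilarity
  same <- multisite_bray_partition(rbind(a = c(1, 2), b = c(1, 2),
                                         c = c(1, 2)))
  expect_equal(c(same$total, same$balanced, same$gradient), c(0, 0, 0))
})

test_that("multisite partition agrees with the brute-force pair oracle", {
  set.seed(202)
  for (i in 1:50) {
    m <- rand_count_matrix(sample(3:8, 1), sample(5:20, 1))
    got <- multisite_bray_partition(m)
    want <- oracle_multisite(m)
    expect_equal(got$total, unname(want["total"]), tolerance = 1e-12)
    expect_equal(got$balanced, unname(want["balanced"]), tolerance = 1e-12)
    expect_equal(got$gradient, unname(want["gradient"]), tolerance = 1e-12)
    expect_equal(got$total, got$balanced + got$gradient, tolerance = 1e-12)
    expect_true(got$total >= 0 && got$total <= 1)
  }
})

test_that("partition is invariant to plot/species permutation and zero columns", {
  set.seed(203)
  m <- rand_count_matrix(6, 12)
  base <- multisite_bray_partition(m)
  perm <- multisite_bray_partition(m[sample(6), sample(12)])
  expect_equal(perm$total, base$total, tolerance = 1e-12)
  expect_equal(perm$balanced, base$balanced, tolerance = 1e-12)
  padded <- multisite_bray_partition(cbind(m, extra = 0))
  expect_equal(padded$total, base$total, tolerance = 1e-15)
  expect_equal(padded$gradient, base$gradient, tolerance = 1e-15)
})

test_that("all-zero plots are dropped with a message, erroring below 2 plots", {
  m <- rbind(a = c(1, 2, 0), b = c(0, 0, 0), c = c(2, 1, 1))
  expect_message(res <- multisite_bray_partition(m),
                 class = "exclodiv_zero_plot")
  kept <- suppressMessages(multisite_bray_partition(m))
  expect_equal(kept$n_plots, 2L)
  expect_equal(kept$total,
               multisite_bray_partition(m[c(1, 3), ])$total)
  expect_error(suppressMessages(
    multisite_bray_partition(rbind(a = c(1, 1), b = c(0, 0)))),
    class = "exclodiv_insufficient_plots")
})

test_that("on presence/absence data the partition equals the Sorensen family", {
  set.seed(204)
  for (i in 1:30) {
    m <- (rand_count_matrix(sample(3:7, 1), sample(6:15, 1)) > 0) * 1
    m[rowSums(m) == 0, 1] <- 1
    got <- multisite_bray_partition(m)
    want <- oracle_incidence(m)
    expect_equal(got$total, unname(want["total"]), tolerance = 1e-12)
    expect_equal(got$balanced, unname(want["balanced"]), tolerance = 1e-12)
    expect_equal(got$gradient, unname(want["gradient"]), tolerance = 1e-12)
  }
})

test_that("beta_summaries does site/occasion/treatment bookkeeping", {
  cfg <- sim_config(n_sites = 2, n_pairs = 4, months = c(0, 6, 12),
                    pool_size = 30, richness0 = 10,
                    missing_months_by_site = list())
  survey <- simulate_survey(cfg, seed = 21)
  b <- beta_summaries(survey, jackknife = FALSE)
  expect_equal(nrow(b), 2 * 3 * 2)
  expect_true(all(b$ok))
  expect_true(all(b$n_plots == 4))
  expect_equal(b$total, b$balanced + b$gradient, tolerance = 1e-12)
  # row order of the input is immaterial
  shuffled <- survey[sample(nrow(survey)), ]
  expect_equal(beta_summaries(shuffled, jackknife = FALSE), b)
})

test_that("transforming before or after the treatment split is equivalent", {
  cfg <- small_null_cfg()
  survey <- simulate_survey(cfg, seed = 22)
  b <- beta_summaries(survey, jackknife = FALSE)
  for (trt in c("control", "exclusion")) {
    mat <- community_matrix(survey, "ITA", 6, treatment = trt)
    manual <- multisite_bray_partition(hellinger_transform(mat))
    row <- b[b$month == 6 & b$treatment == trt, ]
    expect_equal(row$total, manual$total, tolerance = 1e-12)
    expect_equal(row$balanced, manual$balanced, tolerance = 1e-12)
  }
})

test_that("occasions with too few usable plots are flagged, not fatal", {
  survey <- tibble::tibble(
    site = "S1", pair = rep(rep(c("P1", "P2"), each = 2), 2),
    plot = rep(c("P1C", "P1E", "P2C", "P2E"), 2),
    treatment = rep(c("control", "exclusion"), 4),
    month = rep(c(0L, 6L), each = 4),
    species = "a",
    count = c(1L, 1L, 2L, 3L, 1L, 0L, 2L, 0L)
  )
  b <- suppressMessages(beta_summaries(survey, jackknife = FALSE))
  bad <- b[b$month == 6 & b$treatment == "exclusion", ]
  expect_false(bad$ok)
  expect_true(is.na(bad$total))
  expect_true(all(b$ok[b$month == 0]))
})
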