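#' Pairwise abundance-based Bray-Curtis dissimilarity and its partition
#'
#' For two abundance vectors with component sums `A = sum_s min(x_s, y_s)`
#' (shared abundance), `B = sum(x) - A` and `C = sum(y) - A`:
#' * `total = (B + C) / (2A + B + C)` — Bray-Curtis dissimilarity;
#' * `balanced = min(B, C) / (A + min(B, C))` — balanced variation in
#'   species abundances (the abundance analogue of turnover: some species
#'   gain what others lose);
#' * `gradient = total - balanced` — abundance gradients (the analogue of
#'   nestedness: uniform surplus of one community over the other).
#'
#' @param x,y Equal-length non-negative abundance vectors (raw or
#'   transformed); not both all-zero.
#' @return A one-row tibble with columns `total`, `balanced`, `gradient`,
#'   all in `[0, 1]` with `total = balanced + gradient`.
#' @examples
#' pairwise_bray_partition(c(2, 0, 2), c(1, 1, 0))
#' @export
pairwise_bray_partition <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "exclodiv_beta_error")
  }
  if (anyNA(c(x, y)) || any(c(x, y) < 0)) {
    abort("Abundance vectors must be finite and non-negative.",
          class = "exclodiv_beta_error")
  }
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 && sy == 0) {
    abort("Dissimilarity is undefined for two all-zero communities.",
          class = "exclodiv_beta_error")
  }
  A <- sum(pmin(x, y))
  B <- sx - A
  C <- sy - A
  total <- (B + C) / (2 * A + B + C)
  balanced <- if (A + min(B, C) > 0) min(B, C) / (A + min(B, C)) else 0
  tibble(total = total, balanced = balanced, gradient = total - balanced)
}

#' Multiple-site Bray-Curtis dissimilarity with balanced/gradient partition
#'
#' One joint dissimilarity over all plots of a community matrix, following
#' the multiple-site formulation that accumulates the pairwise component
#' sums over all unordered plot pairs `(j, k)`: with
#' `SA = sum A_jk`, `Smin = sum min(B_jk, C_jk)`, `Smax = sum max(B_jk, C_jk)`,
#'
#' * `total = (Smin + Smax) / (2 SA + Smin + Smax)`
#' * `balanced = Smin / (Smin + SA)`
#' * `gradient = total - balanced`
#'
#' All-zero plots (empty at this occasion) are removed before computation,
#' with a message. For exactly two plots the result equals
#' [pairwise_bray_partition()]. On presence/absence (0/1) matrices the three
#' values coincide with the incidence-based multiple-site Sorensen family
#' (Sorensen dissimilarity, Simpson turnover, nestedness-resultant).
#'
#' @param matrix A non-negative plots x species matrix (>= 2 non-empty
#'   plots), e.g. a Hellinger-transformed slice from [community_matrix()].
#' @return A one-row tibble: `site`, `month`, `treatment` (from matrix
#'   metadata, `NA` if absent), `n_plots`, `total`, `balanced`, `gradient`.
#' @examples
#' m <- rbind(p1 = c(2, 0, 2), p2 = c(1, 1, 0))
#' multisite_bray_partition(m)
#' @export
multisite_bray_partition <- function(matrix) {
  if (!is.matrix(matrix) || anyNA(matrix) || any(matrix < 0)) {
    abort("Community matrix values must be finite and non-negative.",
          class = "exclodiv_matrix_error")
  }
  tot <- rowSums(matrix)
  if (any(tot == 0)) {
    inform(sprintf("Removing %d all-zero plot(s) before multiple-site dissimilarity: %s",
                   sum(tot == 0),
                   paste(rownames(matrix)[tot == 0], collapse = ", ")),
           class = "exclodiv_zero_plot")
    matrix <- matrix[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  n <- nrow(matrix)
  if (n < 2) {
    abort(sprintf("Multiple-site dissimilarity needs >= 2 non-empty plots (site %s, month %s, treatment %s).",
                  attr(matrix, "site") %||% NA, attr(matrix, "month") %||% NA,
                  attr(matrix, "treatment") %||% NA),
          class = "exclodiv_insufficient_plots")
  }
  # pairwise component sums via the Manhattan-distance identity
  # A_jk = (tot_j + tot_k - sum_s |x_js - x_ks|) / 2
  d <- as.vector(stats::dist(matrix, method = "manhattan"))
  pairs <- combn(n, 2)
  tj <- tot[pairs[1, ]]
  tk <- tot[pairs[2, ]]
  A <- (tj + tk - d) / 2
  minBC <- pmin(tj, tk) - A
  maxBC <- pmax(tj, tk) - A
  SA <- sum(A); Smin <- sum(minBC); Smax <- sum(maxBC)
  total <- (Smin + Smax) / (2 * SA + Smin + Smax)
  balanced <- if (Smin + SA > 0) Smin / (Smin + SA) else 0
  tibble(
    site = attr(matrix, "site") %||% NA_character_,
    month = attr(matrix, "month") %||% NA_integer_,
    treatment = attr(matrix, "treatment") %||% NA_character_,
    n_plots = n, total = total, balanced = balanced,
    gradient = total - balanced
  )
}

#' Multiple-site beta diversity summaries per site, occasion and treatment
#'
#' For every site x survey month, builds the community matrix on the
#' site-wide species union, applies the Hellinger transformation (row-wise,
#' so transforming before or after the treatment split is equivalent), and
#' computes one multiple-site partition per treatment. Optionally attaches
#' plot-level leave-one-out jackknife standard errors and approximate
#' confidence intervals for each component.
#'
#' Occasions where a treatment has fewer than two usable (non-empty) plots
#' yield a flagged row (`ok = FALSE`, `NA` values) rather than an error.
#'
#' @param survey A survey tibble.
#' @param transformed Apply the Hellinger transformation first (default
#'   `TRUE`).
#' @param jackknife Attach jackknife columns (default `TRUE`).
#' @param ci_level Confidence level for jackknife intervals.
#' @return A tibble with one row per site x month x treatment: `n_plots`,
#'   `total`, `balanced`, `gradient`, `ok`, and (when `jackknife`)
#'   `se_total`, `ci_total_low`, `ci_total_high` and likewise for
#'   `balanced` and `gradient`.
#' @examples
#' survey <- simulate_survey(sim_config(n_sites = 1, n_pairs = 4,
#'   months = c(0, 6), pool_size = 40, richness0 = 12))
#' beta_summaries(survey, jackknife = FALSE)
#' @export
beta_summaries <- function(survey, transformed = TRUE, jackknife = TRUE,
                           ci_level = 0.95) {
  survey <- validate_survey(survey)
  slices <- survey |> distinct(.data$site, .data$month) |>
    arrange(.data$site, .data$month)
  out <- purrr::pmap(slices, function(site, month) {
    mat <- community_matrix(survey, site, month)
    if (transformed) mat <- hellinger_transform(mat)
    meta <- attr(mat, "meta")
    purrr::map(treatment_levels, function(trt) {
      sub <- mat[meta$plot[meta$treatment == trt], , drop = FALSE]
      attr(sub, "site") <- site
      attr(sub, "month") <- month
      attr(sub, "treatment") <- trt
      beta_one_slice(sub, jackknife = jackknife, ci_level = ci_level)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out) |>
    arrange(.data$site, .data$month, .data$treatment)
}

beta_one_slice <- function(mat, jackknife, ci_level) {
  na_row <- tibble(
    site = attr(mat, "site"), month = attr(mat, "month"),
    treatment = attr(mat, "treatment"),
    n_plots = sum(rowSums(mat) > 0),
    total = NA_real_, balanced = NA_real_, gradient = NA_real_, ok = FALSE
  )
  res <- tryCatch(
    multisite_bray_partition(mat),
    exclodiv_insufficient_plots = function(e) NULL
  )
  if (is.null(res)) {
    out <- na_row
  } else {
    out <- mutate(res, ok = TRUE)
  }
  if (!jackknife) return(out)
  jk_cols <- c("se_total", "ci_total_low", "ci_total_high",
               "se_balanced", "ci_balanced_low", "ci_balanced_high",
               "se_gradient", "ci_gradient_low", "ci_gradient_high")
  if (!out$ok[1] || out$n_plots[1] < 3) {
    out[jk_cols] <- NA_real_
    return(out)
  }
  keep <- rowSums(mat) > 0
  jk <- jackknife_partition(mat[keep, , drop = FALSE], ci_level = ci_level)
  dplyr::bind_cols(out, jk)
}

# leave-one-out jackknife of all three partition components at once
jackknife_partition <- function(mat, ci_level) {
  n <- nrow(mat)
  full <- multisite_bray_partition(mat)
  loo <- purrr::map(seq_len(n), function(i) {
    multisite_bray_partition(mat[-i, , drop = FALSE])
  }) |> dplyr::bind_rows()
  z <- qnorm((1 + ci_level) / 2)
  out <- list()
  for (comp in c("total", "balanced", "gradient")) {
    pseudo <- n * full[[comp]] - (n - 1) * loo[[comp]]
    se <- sqrt(sum((pseudo - mean(pseudo))^2) / (n * (n - 1)))
    out[[paste0("se_", comp)]] <- se
    out[[paste0("ci_", comp, "_low")]] <- full[[comp]] - z * se
    out[[paste0("ci_", comp, "_high")]] <- full[[comp]] + z * se
  }
  as_tibble(out)
}
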