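#' Plot-level alpha diversity indices for one community matrix
#'
#' Computes, for each plot (row), species richness, the Shannon index
#' (natural-log units) and the inverse Simpson index. Richness is always the
#' number of species with positive raw abundance. By default (matching the
#' stated order of operations of exclosure analyses that transform before
#' every diversity metric) Shannon and inverse Simpson are evaluated on the
#' Hellinger-transformed row renormalised to proportions
#' `p_i = h_i / sum(h)`; with `transformed = FALSE` they use raw-count
#' proportions. Empty plots get richness 0, Shannon 0, inverse Simpson `NA`,
#' and are flagged `degenerate`.
#'
#' @param matrix A raw (untransformed) non-negative community matrix, as from
#'   [community_matrix()].
#' @param transformed Compute Shannon / inverse Simpson on Hellinger
#'   proportions (default `TRUE`) or raw proportions.
#' @return A tibble with one row per plot: `plot`, `richness`, `shannon`,
#'   `inv_simpson`, `degenerate`, plus `site`, `month`, `pair`, `treatment`
#'   when the matrix carries that metadata.
#' @examples
#' m <- rbind(a = c(5, 5, 5, 5), b = c(10, 0, 0, 0))
#' alpha_indices(m)
#' @export
alpha_indices <- function(matrix, transformed = TRUE) {
  if (anyNA(matrix) || any(matrix < 0)) {
    abort("Community matrix values must be finite and non-negative.",
          class = "exclodiv_matrix_error")
  }
  richness <- as.integer(rowSums(matrix > 0))
  basis <- if (transformed) hellinger_transform(matrix) else matrix
  shannon <- unname(suppressWarnings(vegan::diversity(basis, index = "shannon")))
  inv_simpson <- unname(suppressWarnings(
    vegan::diversity(basis, index = "invsimpson")))
  degenerate <- rowSums(matrix) == 0
  shannon[degenerate] <- 0
  inv_simpson[degenerate] <- NA_real_

  out <- tibble(
    plot = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
    richness = richness, shannon = shannon, inv_simpson = inv_simpson,
    degenerate = unname(degenerate)
  )
  meta <- attr(matrix, "meta")
  if (!is.null(meta)) {
    out <- out |>
      left_join(meta, by = "plot") |>
      mutate(site = attr(matrix, "site"), month = attr(matrix, "month")) |>
      select("site", "pair", "plot", "treatment", "month", everything())
  }
  out
}

#' Alpha diversity table for a whole survey
#'
#' One row per plot and survey occasion, computed site by site on the
#' site-wide species union (see [community_matrix()]).
#'
#' @param survey A survey tibble (validated with [validate_survey()]).
#' @param transformed Passed to [alpha_indices()].
#' @return A tibble of per-plot alpha records sorted by site, month,
#'   treatment, plot.
#' @examples
#' survey <- simulate_survey(sim_config(n_sites = 1, n_pairs = 3,
#'   months = c(0, 6), pool_size = 30, richness0 = 10))
#' alpha_table(survey)
#' @export
alpha_table <- function(survey, transformed = TRUE) {
  survey <- validate_survey(survey)
  slices <- survey |> distinct(.data$site, .data$month) |>
    arrange(.data$site, .data$month)
  out <- purrr::pmap(slices, function(site, month) {
    alpha_indices(community_matrix(survey, site, month),
                  transformed = transformed)
  })
  dplyr::bind_rows(out) |>
    arrange(.data$site, .data$month, .data$treatment, .data$plot)
}
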