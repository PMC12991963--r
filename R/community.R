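#' Build a plots-by-species community matrix for one site and occasion
#'
#' Slices a survey table to one site and survey month and spreads it into a
#' plots x species abundance matrix. Columns are the site-wide species union
#' (every species observed at the site at any occasion) so matrices from
#' different occasions are column-compatible; species never observed in the
#' slice appear as zero columns, which leave all diversity quantities
#' unchanged.
#'
#' @param survey A validated survey tibble.
#' @param site Site label to slice.
#' @param month Survey month to slice.
#' @param treatment Optional treatment to restrict the plots to.
#' @param species Optional character vector fixing the column set (defaults
#'   to the site-wide species union).
#' @return A numeric matrix with plot rownames and species colnames, and
#'   attributes `site`, `month`, `treatment`, and `meta` (a tibble mapping
#'   plots to pair and treatment).
#' @examples
#' survey <- simulate_survey(sim_config(n_sites = 1, n_pairs = 3,
#'   months = c(0, 6), pool_size = 30, richness0 = 10))
#' m <- community_matrix(survey, site = "ITA", month = 0)
#' dim(m)
#' @export
community_matrix <- function(survey, site, month, treatment = NULL,
                             species = NULL) {
  site_rows <- survey[survey$site == site, , drop = FALSE]
  if (nrow(site_rows) == 0) {
    abort(sprintf("No survey rows for site '%s'.", site),
          class = "exclodiv_slice_error")
  }
  species <- species %||% sort(unique(site_rows$species))
  slice <- site_rows[site_rows$month == month, , drop = FALSE]
  if (!is.null(treatment)) {
    slice <- slice[slice$treatment %in% treatment, , drop = FALSE]
  }
  if (nrow(slice) == 0) {
    abort(sprintf("No survey rows for site '%s' at month %s.", site, month),
          class = "exclodiv_slice_error")
  }
  meta <- slice |>
    distinct(.data$plot, .data$pair, .data$treatment) |>
    arrange(.data$plot)
  mat <- matrix(0, nrow = nrow(meta), ncol = length(species),
                dimnames = list(meta$plot, species))
  mat[cbind(match(slice$plot, meta$plot), match(slice$species, species))] <-
    slice$count
  attr(mat, "site") <- site
  attr(mat, "month") <- month
  attr(mat, "treatment") <- if (is.null(treatment)) NA_character_ else treatment
  attr(mat, "meta") <- meta
  mat
}

#' Hellinger transformation of a community matrix
#'
#' Row-wise map `x_ij -> sqrt(x_ij / sum_j x_ij)`: each plot's abundances
#' become square-rooted relative abundances, down-weighting dominant species
#' and making community data suitable for linear methods. Rows with a
#' positive total come out with unit Euclidean norm; all-zero rows (empty
#' plots) map to all-zero rows by convention.
#'
#' @param matrix A non-negative plots x species matrix.
#' @return The transformed matrix (attributes preserved).
#' @examples
#' hellinger_transform(rbind(c(4, 1, 0), c(1, 1, 1)))
#' @export
hellinger_transform <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix.", class = "exclodiv_matrix_error")
  }
  if (anyNA(matrix) || any(!is.finite(matrix)) || any(matrix < 0)) {
    abort("Community matrix values must be finite and non-negative.",
          class = "exclodiv_matrix_error")
  }
  rs <- rowSums(matrix)
  scale <- ifelse(rs > 0, rs, 1)          # empty plots stay all-zero
  out <- sqrt(sweep(matrix, 1, scale, "/"))
  attributes(out) <- attributes(matrix)
  out
}
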