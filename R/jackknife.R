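#' Plot-level leave-one-out jackknife for a multiple-site statistic
#'
#' Computes jackknife pseudo-values for any scalar statistic of a
#' plots x species matrix: with full-sample value `theta` and leave-one-out
#' values `theta_(-i)`, the pseudo-values are
#' `p_i = n * theta - (n - 1) * theta_(-i)`; the standard error is
#' `sqrt(sum((p_i - mean(p))^2) / (n (n - 1)))` and the approximate
#' confidence interval uses a normal multiplier. By default the interval is
#' centred on the full-sample estimate; `center = "pseudo_mean"` centres it
#' on the (bias-corrected) pseudo-value mean instead.
#'
#' @param matrix A plots x species matrix with at least 3 rows, so every
#'   leave-one-out subset retains >= 2 plots.
#' @param statistic A function of a matrix returning a single finite number,
#'   e.g. `function(m) multisite_bray_partition(m)$total`.
#' @param ci_level Confidence level (default 0.95).
#' @param center `"estimate"` (default) or `"pseudo_mean"`.
#' @return An object of class `exclo_jackknife`: a list with `estimate`,
#'   `pseudo_mean`, `se`, `ci_low`, `ci_high`, `n`, `loo_values`.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(1, 1), c = c(2, 1))
#' jackknife_statistic(m, function(x) mean(rowSums(x)))
#' @export
jackknife_statistic <- function(matrix, statistic, ci_level = 0.95,
                                center = c("estimate", "pseudo_mean")) {
  center <- match.arg(center)
  if (!is.matrix(matrix) || nrow(matrix) < 3) {
    abort("Jackknife needs a matrix with at least 3 plots.",
          class = "exclodiv_jackknife_error")
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("`ci_level` must be in (0, 1).", class = "exclodiv_jackknife_error")
  }
  n <- nrow(matrix)
  plot_ids <- rownames(matrix) %||% as.character(seq_len(n))
  theta <- statistic(matrix)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    abort("`statistic` must return a single finite number.",
          class = "exclodiv_jackknife_error")
  }
  loo <- vapply(seq_len(n), function(i) {
    tryCatch(
      statistic(matrix[-i, , drop = FALSE]),
      error = function(e) {
        abort(sprintf("Statistic failed when dropping plot '%s': %s",
                      plot_ids[i], conditionMessage(e)),
              class = "exclodiv_jackknife_error")
      })
  }, numeric(1))
  pseudo <- n * theta - (n - 1) * loo
  pseudo_mean <- mean(pseudo)
  se <- sqrt(sum((pseudo - pseudo_mean)^2) / (n * (n - 1)))
  z <- qnorm((1 + ci_level) / 2)
  mid <- if (center == "estimate") theta else pseudo_mean
  structure(
    list(estimate = theta, pseudo_mean = pseudo_mean, se = se,
         ci_low = mid - z * se, ci_high = mid + z * se, n = n,
         loo_values = setNames(loo, plot_ids), ci_level = ci_level,
         center = center),
    class = "exclo_jackknife"
  )
}

#' @export
print.exclo_jackknife <- function(x, ...) {
  cat(sprintf("<exclo_jackknife> n = %d plots\n", x$n))
  cat(sprintf("  estimate %.6g (pseudo-value mean %.6g)\n",
              x$estimate, x$pseudo_mean))
  cat(sprintf("  se %.6g, %d%% CI [%.6g, %.6g] (centred on %s)\n",
              x$se, round(100 * x$ci_level), x$ci_low, x$ci_high, x$center))
  invisible(x)
}

#' @export
tidy.exclo_jackknife <- function(x, ...) {
  tibble(estimate = x$estimate, pseudo_mean = x$pseudo_mean, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}
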