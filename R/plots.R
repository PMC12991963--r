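#' Plot mean alpha diversity trajectories by treatment
#'
#' Mean +/- one standard error of a plot-level alpha metric per treatment
#' and survey month, facetted by site — the standard visual check on the
#' treatment-by-time interaction.
#'
#' @param alpha An [alpha_table()] tibble.
#' @param metric Metric column to display.
#' @return A ggplot object.
#' @export
plot_alpha_trends <- function(alpha, metric = "richness") {
  summ <- alpha |>
    filter(is.finite(.data[[metric]])) |>
    group_by(.data$site, .data$month, .data$treatment) |>
    summarise(mean = mean(.data[[metric]]),
              se = sd(.data[[metric]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$month, y = .data$mean,
                                     colour = .data$treatment,
                                     fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "Survey month", y = metric,
                  colour = "Treatment", fill = "Treatment") +
    ggplot2::theme_minimal()
}

#' Plot multiple-site beta diversity trajectories by treatment
#'
#' One line per treatment with the jackknife standard-error ribbon (when
#' available), facetted by site.
#'
#' @param beta A [beta_summaries()] tibble.
#' @param component `"total"`, `"balanced"` or `"gradient"`.
#' @return A ggplot object.
#' @export
plot_beta_trends <- function(beta, component = "total") {
  dat <- filter(beta, is.finite(.data[[component]]))
  se_col <- paste0("se_", component)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$month,
                                         y = .data[[component]],
                                         colour = .data$treatment,
                                         fill = .data$treatment))
  if (se_col %in% names(dat)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[component]] - .data[[se_col]],
                   ymax = .data[[component]] + .data[[se_col]]),
      alpha = 0.2, colour = NA)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "Survey month",
                  y = sprintf("Multiple-site beta diversity (%s)", component),
                  colour = "Treatment", fill = "Treatment") +
    ggplot2::theme_minimal()
}

#' Forest plot of pairwise cross-site contrasts
#'
#' Each point is the difference of two site-specific treatment-by-time
#' interaction estimates with its confidence interval; intervals crossing
#' zero indicate no detectable cross-site difference.
#'
#' @param contrasts A [pairwise_contrasts()] tibble (one or several metrics).
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  dat <- mutate(contrasts,
                pair = paste(.data$site_x, "-", .data$site_y),
                significant = .data$p < 0.05)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diff, y = .data$pair,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "Difference in interaction estimate (site X - site Y)",
                  y = NULL, colour = "p < 0.05") +
    ggplot2::theme_minimal()
}
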