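#' Validate a long-format survey table
#'
#' Checks the schema and invariants of the pipeline's single input currency:
#' one row per (site, pair, plot, treatment, month, species) with a
#' non-negative integer count. Violations are reported together with the
#' offending row numbers.
#'
#' Checked invariants: required columns present; counts are non-negative
#' integers; treatments are `"control"`/`"exclusion"`; months are
#' non-negative integers; the key (site, pair, plot, treatment, month,
#' species) is unique; each plot keeps a single (pair, treatment) identity;
#' and every (site, pair) has exactly one control and one exclusion plot.
#'
#' @param x A data frame, or the path of a CSV file with header
#'   `site,pair,plot,treatment,month,species,count`.
#' @return The validated survey as a tibble (typed columns, invisibly the
#'   same data). Errors of class `exclodiv_survey_error` describe every
#'   detected problem.
#' @examples
#' survey <- simulate_survey(scenario_preset("null", n_sites = 1,
#'   n_pairs = 3, months = c(0, 6), pool_size = 30, richness0 = 10))
#' validate_survey(survey)
#' @export
validate_survey <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- read_survey(x, validate = FALSE)
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame or a CSV path.",
          class = "exclodiv_survey_error")
  }
  required <- c("site", "pair", "plot", "treatment", "month", "species",
                "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Survey is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "exclodiv_survey_error")
  }
  x <- as_tibble(x)[required]
  problems <- character()
  row_note <- function(rows, what) {
    sprintf("%s (rows %s%s)", what,
            paste(head(rows, 5), collapse = ", "),
            if (length(rows) > 5) ", ..." else "")
  }

  bad <- which(!is.finite(x$count) | x$count < 0 | x$count != round(x$count))
  if (length(bad) > 0) {
    problems <- c(problems, row_note(bad, "counts must be non-negative integers"))
  }
  bad <- which(!x$treatment %in% treatment_levels)
  if (length(bad) > 0) {
    problems <- c(problems,
                  row_note(bad, "treatment must be 'control' or 'exclusion'"))
  }
  bad <- which(!is.finite(x$month) | x$month < 0 | x$month != round(x$month))
  if (length(bad) > 0) {
    problems <- c(problems, row_note(bad, "months must be non-negative integers"))
  }
  key <- paste(x$site, x$pair, x$plot, x$treatment, x$month, x$species,
               sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad) > 0) {
    problems <- c(problems,
                  row_note(bad, "duplicated (site, pair, plot, treatment, month, species) key"))
  }

  plot_id <- distinct(x, .data$site, .data$pair, .data$plot, .data$treatment)
  multi <- plot_id |>
    count(.data$site, .data$plot) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    problems <- c(problems,
                  sprintf("plots mapped to multiple (pair, treatment) identities: %s",
                          paste(head(paste(multi$site, multi$plot, sep = "/"), 5),
                                collapse = ", ")))
  }
  pairing <- plot_id |>
    count(.data$site, .data$pair, .data$treatment) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "n",
                       values_fill = 0L)
  for (lev in treatment_levels) {
    if (!lev %in% names(pairing)) pairing[[lev]] <- 0L
  }
  unpaired <- filter(pairing, .data$control != 1L | .data$exclusion != 1L)
  if (nrow(unpaired) > 0) {
    problems <- c(problems,
                  sprintf("pairs without exactly one control and one exclusion plot: %s",
                          paste(head(paste(unpaired$site, unpaired$pair, sep = "/"), 5),
                                collapse = ", ")))
  }

  if (length(problems) > 0) {
    abort(c("Invalid survey table:", setNames(problems, rep("x", length(problems)))),
          class = "exclodiv_survey_error")
  }
  out <- mutate(x,
                site = as.character(.data$site),
                pair = as.character(.data$pair),
                plot = as.character(.data$plot),
                treatment = as.character(.data$treatment),
                month = as.integer(.data$month),
                species = as.character(.data$species),
                count = as.integer(.data$count))
  # drop reader-specific classes/attributes so equal surveys compare equal
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Read / write survey CSV files
#'
#' UTF-8 CSV with header `site,pair,plot,treatment,month,species,count`.
#'
#' @param path File path.
#' @param validate Run [validate_survey()] after reading (default `TRUE`).
#' @return `read_survey()` returns the survey tibble; `write_survey()`
#'   returns `path` invisibly.
#' @export
read_survey <- function(path, validate = TRUE) {
  x <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), pair = readr::col_character(),
    plot = readr::col_character(), treatment = readr::col_character(),
    month = readr::col_integer(), species = readr::col_character(),
    count = readr::col_integer()))
  if (validate) validate_survey(x) else x
}

#' @param survey A survey tibble.
#' @rdname read_survey
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path)
  invisible(path)
}
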