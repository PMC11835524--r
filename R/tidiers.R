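#' @export
print.kinloss_result <- function(x, ...) {
  s <- x$settings
  cat("<kinloss_result>\n")
  cat("  incidence years: ", min(s$years), "-", max(s$years), "\n",
      sep = "")
  cat("  prevalence years:", paste(s$prevalence_years, collapse = ", "),
      "\n")
  if (!is.null(s$n_rep) && s$n_rep > 1) {
    cat("  replicates:", s$n_rep, "(co-monotone Poisson)\n")
  }
  cat("  headline series:\n")
  print(tidyr::pivot_wider(
    dplyr::filter(x$summary, year == max(year)),
    names_from = measure, values_from = count
  ), width = 80)
  invisible(x)
}

#' Tidy a pipeline result into a long tibble
#'
#' One row per (year, measure) headline estimate, with 95% uncertainty
#' intervals when the pipeline was run with replicates.
#'
#' @param x A `kinloss_result`.
#' @param ... Unused.
#' @return A tibble `year`, `measure`, `count` (and `median`, `lo95`,
#'   `hi95` when replicated).
#' @export
tidy.kinloss_result <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$summary_ui)) {
    out <- dplyr::left_join(out, x$summary_ui, by = c("year", "measure"))
  }
  out
}

#' One-row summary of a pipeline result
#'
#' @param x A `kinloss_result`.
#' @param ... Unused.
#' @return A one-row tibble with the estimation span, number of
#'   replicates, and the latest-year orphanhood incidence and prevalence.
#' @export
glance.kinloss_result <- function(x, ...) {
  s <- x$settings
  latest <- max(x$summary$year)
  pick <- function(m) {
    v <- x$summary$count[x$summary$year == latest & x$summary$measure == m]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    first_year = min(s$years), last_year = max(s$years),
    n_rep = s$n_rep %||% 1L, seed = s$seed,
    orphanhood_incidence_latest = pick("orphanhood_incidence"),
    orphanhood_prevalence_latest = pick("orphanhood_prevalence")
  )
}

#' Plot the headline kin-loss series
#'
#' Line plot of the headline incidence and prevalence series over time,
#' with 95% uncertainty ribbons when the result carries replicates.
#'
#' @param object A `kinloss_result`.
#' @param measures Optional character vector restricting the measures
#'   shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinloss_result <- function(object, measures = NULL, ...) {
  d <- tidy(object)
  if (!is.null(measures)) d <- dplyr::filter(d, measure %in% measures)
  p <- ggplot2::ggplot(d, ggplot2::aes(year, count, colour = measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "year", y = "children", colour = NULL) +
    ggplot2::theme_minimal()
  if (all(c("lo95", "hi95") %in% names(d))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = lo95, ymax = hi95, fill = measure),
      alpha = 0.15, colour = NA
    ) + ggplot2::labs(fill = NULL)
  }
  p
}

#' @rdname autoplot.kinloss_result
#' @param result A `kinloss_result`.
#' @export
plot_incidence <- function(result) {
  autoplot(result,
           measures = grep("incidence", unique(result$summary$measure),
                           value = TRUE))
}

#' @rdname autoplot.kinloss_result
#' @export
plot_prevalence <- function(result) {
  autoplot(result,
           measures = grep("prevalence", unique(result$summary$measure),
                           value = TRUE))
}

#' Plot incidence by cause over time
#'
#' @param result A `kinloss_result`.
#' @return A ggplot object with one line per cause of death.
#' @export
plot_causes <- function(result) {
  d <- result$incidence |>
    dplyr::group_by(year, cause) |>
    dplyr::summarise(count = sum(new), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(year, count, colour = cause)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "new orphanhood", colour = "cause") +
    ggplot2::theme_minimal()
}
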