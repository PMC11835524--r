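#' Percent change between two values
#'
#' `100 * (new - old) / old`, full precision (round only at the
#' presentation layer). Defined only for positive baselines.
#'
#' @param old,new Numeric vectors; `old` must be > 0.
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(330413, 494036) # 49.5 to one decimal
#' @export
percent_change <- function(old, new) {
  if (any(old <= 0)) {
    stop("percent change undefined for non-positive baseline",
         call. = FALSE)
  }
  100 * (new - old) / old
}

#' Build a trend summary table
#'
#' From long-format estimates (`year`, `measure`, `count`, optional
#' `replicate`) and annual child population sizes, computes counts, rates
#' per 100 children, a `total` row summing the measures, and percent
#' changes between named year pairs. With a `replicate` column every
#' derived quantity (rates, totals, changes) is computed per replicate
#' first and then summarized as median and 95% interval; the point value
#' of a change is the median of per-replicate changes (the
#' change-of-medians is also reported as `change_of_medians` for
#' transparency).
#'
#' @param estimates Tibble `year`, `measure`, `count` (+ `replicate`).
#' @param child_population Tibble `year`, `population`.
#' @param year_pairs Named list of `c(from, to)` pairs, e.g.
#'   `list("2000-2021" = c(2000, 2021))`.
#' @return List of tibbles: `levels` (per year and measure: count and
#'   rate, with 95% UIs when replicated) and `changes` (per pair and
#'   measure: percent change in counts).
#' @export
build_summary <- function(estimates, child_population, year_pairs = NULL) {
  miss <- setdiff(unique(estimates$year), child_population$year)
  if (length(miss)) {
    stop("missing child population for year(s) ",
         paste(sort(miss), collapse = ", "), call. = FALSE)
  }
  has_rep <- "replicate" %in% names(estimates)
  if (!has_rep) estimates$replicate <- 1L
  grp <- c("replicate", "year")
  totals <- estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::mutate(measure = "total")
  long <- dplyr::bind_rows(estimates, totals) |>
    dplyr::left_join(child_population, by = "year") |>
    dplyr::mutate(rate_per_100 = count / population * 100) |>
    dplyr::select(-population)
  changes <- NULL
  if (!is.null(year_pairs)) {
    changes <- purrr::imap_dfr(year_pairs, function(pair, label) {
      long |>
        dplyr::filter(year %in% pair) |>
        tidyr::pivot_wider(id_cols = c(replicate, measure),
                           names_from = year,
                           values_from = c(count, rate_per_100)) |>
        dplyr::mutate(
          period = label,
          change_count = percent_change(
            .data[[paste0("count_", pair[1])]],
            .data[[paste0("count_", pair[2])]]
          ),
          change_rate = percent_change(
            .data[[paste0("rate_per_100_", pair[1])]],
            .data[[paste0("rate_per_100_", pair[2])]]
          )
        ) |>
        dplyr::select(replicate, period, measure, change_count,
                      change_rate)
    })
  }
  if (has_rep) {
    levels <- long |>
      tidyr::pivot_longer(dplyr::all_of(c("count", "rate_per_100")),
                          names_to = "quantity") |>
      summarize_replicates(value = "value",
                           by = c("year", "measure", "quantity"))
    if (!is.null(changes)) {
      med_of_changes <- changes |>
        tidyr::pivot_longer(
          dplyr::all_of(c("change_count", "change_rate")),
          names_to = "quantity"
        ) |>
        summarize_replicates(value = "value",
                             by = c("period", "measure", "quantity"))
      change_of_medians <- long |>
        dplyr::group_by(year, measure) |>
        dplyr::summarise(count = median(count), .groups = "drop")
      com <- purrr::imap_dfr(year_pairs, function(pair, label) {
        w <- tidyr::pivot_wider(
          dplyr::filter(change_of_medians, year %in% pair),
          names_from = year, values_from = count
        )
        tibble::tibble(
          period = label, measure = w$measure,
          change_of_medians = percent_change(
            w[[as.character(pair[1])]], w[[as.character(pair[2])]]
          )
        )
      })
      changes <- dplyr::left_join(
        med_of_changes, com, by = c("period", "measure")
      )
    }
  } else {
    levels <- dplyr::select(long, -replicate)
    if (!is.null(changes)) changes <- dplyr::select(changes, -replicate)
  }
  list(levels = levels, changes = changes)
}
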