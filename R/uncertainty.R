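#' Co-monotone Poisson replicates of a count table
#'
#' Generates `n_rep` Poisson draws around each count and couples the
#' replicates by rank: within every cell the draws are sorted, and
#' replicate `k` receives the `k`-th order statistic in every year of the
#' cell's stratum. Each replicate is therefore consistently high or low
#' across years, maximizing positive temporal dependence, while the
#' marginal distribution in every cell is exactly Poisson.
#'
#' @param counts Count tibble (`count` column plus stratum columns;
#'   real-valued counts from the comparability adjustment are valid
#'   Poisson means).
#' @param n_rep Number of replicates (>= 2).
#' @param seed Optional integer seed.
#' @return Long tibble: `replicate` (1..n_rep) plus the input columns,
#'   with `count` replaced by the replicate draw.
#' @export
poisson_comonotone <- function(counts, n_rep, seed = NULL) {
  if (n_rep < 2) {
    stop("configuration error: n_rep must be at least 2", call. = FALSE)
  }
  if (any(counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(
    counts$count,
    function(lambda) sort(rpois(n_rep, lambda)),
    numeric(n_rep)
  )
  out <- counts[rep(seq_len(nrow(counts)), each = n_rep), ]
  out$replicate <- rep(seq_len(n_rep), nrow(counts))
  out$count <- as.vector(draws)
  dplyr::relocate(tibble::as_tibble(out), replicate)
}

#' Normal resampling of ratios or survey proportions
#'
#' Draws `n_rep` normal replicates around each median value. 90% margins
#' of error are converted to standard deviations by dividing by 1.645 (the
#' 90% two-sided normal quantile). Draws are truncated at 0, since
#' negative ratios and proportions are meaningless.
#'
#' @param x Tibble containing the value column and an uncertainty column.
#' @param n_rep Number of replicates.
#' @param seed Optional integer seed.
#' @param value_col Name of the median/value column (e.g. `"ratio"`).
#' @param sd_col Name of the uncertainty column.
#' @param moe90 If `TRUE`, `sd_col` holds 90% margins of error and is
#'   divided by 1.645.
#' @return Long tibble with a `replicate` column; `value_col` replaced by
#'   draws.
#' @export
resample_ratios <- function(x, n_rep, seed = NULL, value_col = "ratio",
                            sd_col = "sd", moe90 = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sds <- x[[sd_col]]
  if (any(sds < 0, na.rm = TRUE)) {
    stop("configuration error: negative sd", call. = FALSE)
  }
  sds[is.na(sds)] <- 0
  if (moe90) sds <- sds / moe90_to_sd_factor()
  med <- x[[value_col]]
  draws <- vapply(
    seq_along(med),
    function(i) pmax(0, rnorm(n_rep, med[i], sds[i])),
    numeric(n_rep)
  )
  out <- x[rep(seq_len(nrow(x)), each = n_rep), ]
  out$replicate <- rep(seq_len(n_rep), nrow(x))
  out[[value_col]] <- as.vector(draws)
  dplyr::relocate(tibble::as_tibble(out), replicate)
}

#' @rdname resample_ratios
#' @details The conversion factor is the conventional two-sided 90%
#'   normal quantile 1.645 used in ACS documentation (so a margin of
#'   error of 16.45 maps to a standard deviation of exactly 10).
#' @export
moe90_to_sd_factor <- function() 1.645

#' Summarize a replicate ensemble
#'
#' Pointwise median and 95% uncertainty interval (2.5% and 97.5%
#' quantiles, linear interpolation between order statistics — R quantile
#' type 7) per output cell. Derived quantities such as percent changes
#' must be computed per replicate *before* summarizing.
#'
#' @param x Long tibble with a `replicate` column.
#' @param value Name of the value column to summarize.
#' @param by Character vector of grouping columns; defaults to all columns
#'   other than `replicate` and `value`.
#' @return Tibble of `by` columns plus `median`, `lo95`, `hi95`.
#' @export
summarize_replicates <- function(x, value = "count", by = NULL) {
  if (!nrow(x)) stop("empty replicate ensemble", call. = FALSE)
  if (length(unique(x$replicate)) < 2) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  if (is.null(by)) by <- setdiff(names(x), c("replicate", value))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      median = median(.data[[value]]),
      lo95 = quantile(.data[[value]], 0.025, type = 7, names = FALSE),
      hi95 = quantile(.data[[value]], 0.975, type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' @importFrom stats qnorm
NULL
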