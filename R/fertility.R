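#' Compute stratified fertility (or mortality) rates
#'
#' Rates are events per person-year: the count of live births (or deaths)
#' divided by the population size in the same (year, age band, sex,
#' race/ethnicity) stratum. Strata present in the population but absent
#' from the event table get rate 0; an event count with zero population is
#' an estimation error.
#'
#' @param events Natality (or mortality) tibble: `year`, `age_band`, `sex`,
#'   `race_ethnicity`, `count` (natality columns `parent_age_band` /
#'   `parent_sex` are accepted and normalized).
#' @param population Population tibble on the same strata.
#' @param zero_outside If `TRUE` (default), rates are forced to 0 outside
#'   the reproductive band ranges (mothers 15-49, fathers 15-77).
#' @return Tibble `year`, `age_band`, `sex`, `race_ethnicity`, `rate`.
#' @examples
#' b <- tibble::tibble(year = 2000, age_band = "20-24", sex = "female",
#'                     race_ethnicity = "all", count = 100)
#' p <- tibble::tibble(year = 2000, age_band = "20-24", sex = "female",
#'                     race_ethnicity = "all", count = 1000)
#' compute_fertility(b, p)$rate # 0.1
#' @export
compute_fertility <- function(events, population, zero_outside = TRUE) {
  nm <- names(events)
  nm[nm == "parent_age_band"] <- "age_band"
  nm[nm == "parent_sex"] <- "sex"
  names(events) <- nm
  keys <- intersect(c("year", "state", "age_band", "sex", "race_ethnicity"),
                    names(population))
  out <- population |>
    dplyr::select(dplyr::all_of(keys), count_p = count) |>
    dplyr::full_join(
      dplyr::select(events, dplyr::all_of(keys), count_b = count),
      by = keys
    ) |>
    dplyr::mutate(count_b = dplyr::coalesce(.data$count_b, 0))
  no_pop <- is.na(out$count_p) | out$count_p == 0
  if (any(no_pop & out$count_b > 0)) {
    stop("estimation error: births observed in stratum with zero population",
         call. = FALSE)
  }
  if (any(no_pop)) {
    warning("zero-population stratum with zero events: rate set to 0")
  }
  out <- out |>
    dplyr::mutate(rate = ifelse(no_pop, 0, .data$count_b / count_p)) |>
    dplyr::select(dplyr::all_of(keys), rate)
  if (zero_outside && all(c("sex", "age_band") %in% keys)) {
    bb <- band_bounds(out$age_band)
    cap <- ifelse(out$sex == "female", 49, 77)
    out$rate[bb$lo < 15 | bb$lo > cap] <- 0
  }
  out
}

#' Extend a fertility-rate series back in time
#'
#' Years before the reference year that are not directly observed are
#' assigned the reference year's rates (the constant-before assumption used
#' when historic population denominators are unavailable). Observed rates
#' for earlier years, when supplied (the historic-fertility sensitivity
#' mode), take precedence over the backfill.
#'
#' @param rates Fertility-rate tibble (`year`, `age_band`, `sex`,
#'   `race_ethnicity`, `rate`).
#' @param reference_year Year whose rates are copied backwards; must be
#'   present in `rates`.
#' @param from_year Earliest year the extended table must cover.
#' @return Tibble covering `from_year` through the latest observed year.
#' @export
extend_historic <- function(rates, reference_year, from_year) {
  if (!reference_year %in% rates$year) {
    stop("reference_year ", reference_year, " not present in rates",
         call. = FALSE)
  }
  if (from_year > reference_year) {
    stop("range error: from_year is after reference_year", call. = FALSE)
  }
  ref <- dplyr::filter(rates, year == reference_year)
  need <- setdiff(seq(from_year, reference_year - 1), unique(rates$year))
  fill <- purrr::map_dfr(need, function(y) dplyr::mutate(ref, year = y))
  dplyr::bind_rows(rates, fill) |>
    dplyr::arrange(dplyr::across(dplyr::any_of(
      c("year", "sex", "race_ethnicity", "age_band")
    )))
}

#' Dampen fertility rates near an individual's death
#'
#' Sensitivity-analysis adjustment coupling fertility to imminent death:
#' the rate is multiplied by a factor that tapers along a cumulative
#' logistic curve from 1 at `onset` years before death down to the
#' scenario floor (0 or 0.5) in the death year itself. Years further from
#' death than the onset are unchanged; scenario `"none"` is the identity.
#'
#' @param rate Numeric vector of fertility rates.
#' @param years_before_death Non-negative integer vector: 0 means the death
#'   year.
#' @param scenario One of `"none"`, `"zero_at_death"`, `"half_at_death"`.
#' @param onset Years before death at which the taper begins (0, 1 or 3 in
#'   the study design).
#' @param scale Logistic scale in years controlling the taper shape (the
#'   scenario endpoints, not the shape, drive the sensitivity bounds).
#' @return Adjusted rate vector, bounded in `[floor * rate, rate]` and
#'   monotone non-increasing as death approaches.
#' @examples
#' dampen_fertility(0.1, 0, "zero_at_death") # 0
#' dampen_fertility(0.1, 0, "half_at_death") # 0.05
#' dampen_fertility(0.1, 5, "zero_at_death", onset = 3) # 0.1
#' @export
dampen_fertility <- function(rate, years_before_death,
                             scenario = c("none", "zero_at_death",
                                          "half_at_death"),
                             onset = 0, scale = 0.5) {
  scenario <- match.arg(scenario)
  if (onset < 0) stop("configuration error: negative onset", call. = FALSE)
  if (any(years_before_death < 0)) {
    stop("years_before_death must be non-negative", call. = FALSE)
  }
  if (identical(scenario, "none")) return(rate)
  floor_f <- if (identical(scenario, "zero_at_death")) 0 else 0.5
  t <- years_before_death
  w <- rep(1, length(t))
  w[t <= 0] <- 0
  inside <- t > 0 & t < onset
  if (any(inside)) {
    lo <- stats::plogis((0 - onset / 2) / scale)
    hi <- stats::plogis((onset - onset / 2) / scale)
    w[inside] <- (stats::plogis((t[inside] - onset / 2) / scale) - lo) /
      (hi - lo)
  }
  rate * (floor_f + (1 - floor_f) * w)
}
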