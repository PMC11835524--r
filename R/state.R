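#' Impute suppressed small counts
#'
#' Public state-level tabulations mask counts below 10. Suppressed cells
#' are imputed with 2 in the state analysis and with 1 in the finer
#' state-by-race analysis; the suppression flag is retained for audit.
#'
#' @param counts Count tibble with a logical `suppressed` column.
#' @param mode `"state"` (impute 2) or `"state_race"` (impute 1).
#' @return Tibble with imputed counts and the `suppressed` flag kept.
#' @export
impute_suppressed <- function(counts, mode = c("state", "state_race")) {
  mode <- match.arg(mode)
  fill <- if (identical(mode, "state")) 2 else 1
  if (!"suppressed" %in% names(counts)) counts$suppressed <- FALSE
  counts$suppressed[is.na(counts$suppressed)] <- FALSE
  counts$count[counts$suppressed] <- fill
  counts
}

#' Rescale state counts to the national total
#'
#' Computes per-stratum ratios `eta = D_national / sum_states(D_state)`
#' over (year, age band, sex, cause) and applies them so state counts sum
#' exactly to the national count. Strata whose state sum is zero while the
#' national count is positive (fully suppressed strata) are flagged,
#' `eta` falls back to 1 and a warning is logged.
#'
#' @param state_counts Count tibble with a `state` column.
#' @param national_counts Count tibble on the matching strata, without
#'   `state`.
#' @return List with `counts` (adjusted state tibble, extra column
#'   `count_raw`) and `adjustment` (audit tibble of strata, `eta`,
#'   `flag`).
#' @export
rescale_to_national <- function(state_counts, national_counts) {
  keys <- intersect(setdiff(names(national_counts),
                            c("count", "suppressed")),
                    names(state_counts))
  st_sum <- state_counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(state_sum = sum(count), .groups = "drop")
  adj <- national_counts |>
    dplyr::select(dplyr::all_of(keys), national = count) |>
    dplyr::inner_join(st_sum, by = keys) |>
    dplyr::mutate(
      flag = .data$state_sum == 0 & .data$national > 0,
      eta = ifelse(.data$flag | .data$state_sum == 0, 1,
                   .data$national / .data$state_sum)
    )
  if (any(adj$flag)) {
    warning(sum(adj$flag), " stratum/strata fully suppressed across ",
            "states; eta set to 1 and flagged")
  }
  counts <- state_counts |>
    dplyr::left_join(dplyr::select(adj, dplyr::all_of(keys), eta, flag),
                     by = keys) |>
    dplyr::mutate(
      eta = dplyr::coalesce(eta, 1),
      flag = dplyr::coalesce(flag, FALSE),
      count_raw = count,
      count = count * eta
    ) |>
    dplyr::select(-eta, -flag)
  list(
    counts = counts,
    adjustment = dplyr::select(adj, dplyr::all_of(keys), eta, flag)
  )
}

#' Interpolate a fertility-rate series with a local-regression smoother
#'
#' Fills missing years of a rate series using tricube-weighted local
#' linear regression (`stats::loess`, degree 1) with a configurable span
#' (0.85 in the study design). Years after the last observation carry the
#' last observed value forward. With fewer than 4 observed points the
#' smoother is unreliable and the series falls back to carry-forward (and
#' carry-backward for leading gaps) with a warning.
#'
#' @param series Tibble with columns `year` and `value`; missing years may
#'   be absent or `NA`.
#' @param span Loess span fraction.
#' @param years Years the output must cover; defaults to the observed
#'   range.
#' @return Tibble `year`, `value` with every requested year filled.
#' @export
smooth_fertility_series <- function(series, span = 0.85, years = NULL) {
  obs <- series |>
    dplyr::filter(!is.na(value)) |>
    dplyr::arrange(year)
  if (is.null(years)) years <- seq(min(obs$year), max(obs$year))
  out <- tibble::tibble(year = years)
  if (nrow(obs) < 4) {
    warning("fewer than 4 observed points; carrying observed values ",
            "forward instead of smoothing")
    idx <- findInterval(years, obs$year)
    idx[idx == 0] <- 1 # leading gap: carry the first value backward
    return(dplyr::mutate(out, value = obs$value[idx]))
  }
  fit <- loess(value ~ year, data = obs, span = span, degree = 1,
               control = stats::loess.control(surface = "direct"))
  interior <- years >= min(obs$year) & years <= max(obs$year)
  out$value <- NA_real_
  out$value[interior] <- predict(fit, tibble::tibble(year = years[interior]))
  out$value[match(obs$year, years)] <- obs$value # keep observed years exact
  # trailing (and leading) gaps carry the nearest observed value
  out$value[years > max(obs$year)] <- obs$value[nrow(obs)]
  out$value[years < min(obs$year)] <- obs$value[1]
  out
}

#' National correction of state-level incidence
#'
#' Compares state incidence summed across states with the race-summed
#' national incidence and corrects each state's estimates by the ratio
#' `nu(y, s, c) = O_national / sum_states(O_state)` — deliberately not
#' age-specific, so within-state age compositions are preserved. After
#' correction, state sums match the national estimates (the study reports
#' residual discrepancies of up to 0.5%).
#'
#' @param state_incidence Tibble with `state` plus `year`, `sex`, `cause`
#'   (and any finer columns such as `age_band`, `child_age`) and `new`.
#' @param national_incidence Tibble with `year`, `sex`, `cause` (race and
#'   other strata summed away or present and summed here) and `new`.
#' @return List with `incidence` (corrected, extra column `new_raw`) and
#'   `adjustment` (tibble `year`, `sex`, `cause`, `nu`, `flag`).
#' @export
state_correction <- function(state_incidence, national_incidence) {
  keys <- intersect(c("year", "sex", "cause"), names(national_incidence))
  nat <- national_incidence |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(national = sum(new), .groups = "drop")
  st <- state_incidence |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(state_sum = sum(new), .groups = "drop")
  adj <- nat |>
    dplyr::inner_join(st, by = keys) |>
    dplyr::mutate(
      flag = .data$state_sum == 0 & .data$national > 0,
      nu = ifelse(.data$state_sum == 0, 1,
                  .data$national / .data$state_sum)
    )
  if (any(adj$flag)) {
    warning(sum(adj$flag), " stratum/strata with zero state incidence; ",
            "nu set to 1 and flagged")
  }
  inc <- state_incidence |>
    dplyr::left_join(dplyr::select(adj, dplyr::all_of(keys), nu), by = keys) |>
    dplyr::mutate(
      nu = dplyr::coalesce(nu, 1),
      new_raw = new,
      new = new * nu
    ) |>
    dplyr::select(-nu)
  list(incidence = inc,
       adjustment = dplyr::select(adj, dplyr::all_of(keys), nu, flag))
}

#' State-level grandparent caregiver loss
#'
#' Applies the national grandparent caregiver-loss formulas per state:
#' type-specific proportions (constant before the first surveyed year)
#' times state deaths at ages 30+, age-disaggregated by the state's own
#' orphanhood age composition.
#'
#' @param props_by_state Caregiver-proportions tibble with a `state`
#'   column (see [caregiver_proportions()]).
#' @param deaths Cause-mapped state mortality with age bands 30+.
#' @param state_orphan_composition State orphanhood incidence by parental
#'   age band ([incidence_by_sex()] with `keep_band = TRUE`, on state
#'   data).
#' @param years Optional years to expand proportions to.
#' @return Age-disaggregated caregiver-loss tibble with `state`.
#' @export
state_grandparent <- function(props_by_state, deaths,
                              state_orphan_composition, years = NULL) {
  props <- props_by_state |>
    dplyr::group_by(state) |>
    dplyr::group_modify(~ caregiver_proportions(.x, years = years)) |>
    dplyr::ungroup()
  g <- grandparent_incidence(props, deaths)
  disaggregate_child_age(g, state_orphan_composition,
                         mode = "cause_specific")
}

#' Reliability screening of state-by-race strata
#'
#' Flags (state, race/ethnicity) strata as unreliable when more than
#' `max_bands` age bands have fewer than `threshold` live births ("small
#' populations"), analogously for deaths ("small death counts"), or when
#' the race-summed incidence falls more than `max_gap` below the state
#' estimate ("large discrepancy in estimates").
#'
#' @param births,deaths Count tibbles by (`state`, `race_ethnicity`,
#'   `age_band`).
#' @param race_state_estimates Tibble `state`, `race_ethnicity`, `new`.
#' @param state_estimates Tibble `state`, `new`.
#' @param threshold Count threshold (20).
#' @param max_bands Maximum allowed number of sub-threshold bands (2;
#'   exclusion requires *more than* this many).
#' @param max_gap Maximum allowed relative shortfall of the race sum
#'   (0.2).
#' @return Tibble `state`, `race_ethnicity`, `flag_small_populations`,
#'   `flag_small_death_counts`, `flag_large_discrepancy`, `include`.
#' @export
reliability_screen <- function(births, deaths, race_state_estimates = NULL,
                               state_estimates = NULL, threshold = 20,
                               max_bands = 2, max_gap = 0.2) {
  count_flags <- function(x) {
    x |>
      dplyr::group_by(state, race_ethnicity, age_band) |>
      dplyr::summarise(count = sum(count), .groups = "drop_last") |>
      dplyr::summarise(n_small = sum(count < threshold), .groups = "drop")
  }
  out <- count_flags(births) |>
    dplyr::mutate(flag_small_populations = .data$n_small > max_bands) |>
    dplyr::select(-n_small) |>
    dplyr::full_join(
      count_flags(deaths) |>
        dplyr::mutate(flag_small_death_counts = .data$n_small > max_bands) |>
        dplyr::select(-n_small),
      by = c("state", "race_ethnicity")
    ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("flag_"),
                                ~ dplyr::coalesce(.x, FALSE)))
  if (!is.null(race_state_estimates) && !is.null(state_estimates)) {
    gap <- race_state_estimates |>
      dplyr::group_by(state) |>
      dplyr::summarise(race_sum = sum(new), .groups = "drop") |>
      dplyr::inner_join(
        state_estimates |>
          dplyr::group_by(state) |>
          dplyr::summarise(state_new = sum(new), .groups = "drop"),
        by = "state"
      ) |>
      dplyr::mutate(
        flag_large_discrepancy =
          (.data$state_new - .data$race_sum) / .data$state_new > max_gap
      ) |>
      dplyr::select(state, flag_large_discrepancy)
    out <- dplyr::left_join(out, gap, by = "state") |>
      dplyr::mutate(flag_large_discrepancy =
                      dplyr::coalesce(.data$flag_large_discrepancy, FALSE))
  } else {
    out$flag_large_discrepancy <- FALSE
  }
  dplyr::mutate(
    out,
    include = !(.data$flag_small_populations |
                  .data$flag_small_death_counts |
                  .data$flag_large_discrepancy)
  )
}
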