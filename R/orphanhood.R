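#' Expected number of children left behind per decedent
#'
#' For a decedent of single age `a`, sex `s` and race/ethnicity `r` in year
#' `y`, the expected number of their children currently aged `b` is the
#' fertility rate of the age band containing `a - b` in the child's birth
#' year `y - b`, multiplied by the probability that a child born in
#' `y - b` survives through age `b`:
#' `C = FR(y - b, band(a - b), s, r) * p_survive(y - b, b)`.
#' Ages `a - b` outside the reproductive range (mothers 15-49, fathers
#' 15-77) contribute 0. Band-level values are the mean of the single-age
#' values over the ages of the band within the sex-specific parental age
#' range (mothers 15-66, fathers 15-94).
#'
#' @param fertility Fertility-rate tibble covering birth years `y - b` for
#'   every requested year `y` and child age `b` (see [extend_historic()]).
#' @param child_survival Tibble `birth_year`, `age`, `p_survive`, where
#'   `p_survive` is survival from birth through age `age` (i.e. to age
#'   `age + 1`); not race-indexed.
#' @param years Integer vector of calendar years to evaluate.
#' @param child_ages Child ages, default 0:17.
#' @param bands Parental age-band set for the band-level aggregation.
#' @return Tibble `year`, `age_band`, `sex`, `race_ethnicity`, `child_age`,
#'   `expected_children` (band level).
#' @export
expected_children <- function(fertility, child_survival, years,
                              child_ages = 0:17, bands = adult_bands()) {
  races <- unique(fertility$race_ethnicity)
  sexes <- intersect(c("female", "male"), unique(fertility$sex))
  grid <- purrr::map_dfr(sexes, function(s) {
    tidyr::expand_grid(
      year = years, sex = s, race_ethnicity = races,
      age = parent_age_range(s), child_age = child_ages
    )
  })
  grid <- grid |>
    dplyr::mutate(
      birth_year = year - child_age,
      age_at_birth = age - child_age,
      fr_band = ifelse(
        sex == "female",
        band_for_age(age_at_birth, mother_bands()),
        band_for_age(age_at_birth, father_bands())
      )
    )
  need_cohorts <- grid |>
    dplyr::filter(!is.na(.data$fr_band)) |>
    dplyr::distinct(birth_year)
  missing_fr <- setdiff(need_cohorts$birth_year, unique(fertility$year))
  if (length(missing_fr)) {
    stop("estimation error: fertility rates missing for birth year(s) ",
         paste(sort(missing_fr), collapse = ", "), call. = FALSE)
  }
  surv <- dplyr::select(child_survival, birth_year, age, p_survive)
  missing_sv <- dplyr::anti_join(
    dplyr::distinct(grid, birth_year, age = child_age), surv,
    by = c("birth_year", "age")
  )
  if (nrow(missing_sv)) {
    stop("estimation error: child survival missing for cohort(s) ",
         paste(sort(unique(missing_sv$birth_year)), collapse = ", "),
         call. = FALSE)
  }
  grid |>
    dplyr::left_join(
      dplyr::select(fertility, birth_year = year, fr_band = age_band, sex,
                    race_ethnicity, rate),
      by = c("birth_year", "fr_band", "sex", "race_ethnicity")
    ) |>
    dplyr::left_join(surv, by = c("birth_year", child_age = "age")) |>
    dplyr::mutate(
      c_single = dplyr::coalesce(rate, 0) * p_survive,
      age_band = band_for_age(age, bands)
    ) |>
    dplyr::filter(!is.na(age_band)) |>
    dplyr::group_by(year, age_band, sex, race_ethnicity, child_age) |>
    dplyr::summarise(expected_children = mean(.data$c_single),
                     .groups = "drop")
}

#' Mid-band mortality hazard from deaths and population
#'
#' Annualized death rate over an age band of width `n` years:
#' `h = D / (n * P)`, the standard life-table mid-band approximation
#' equal to `(1/n) * 2q / (2 - q)` with `q = D / (P + D/2)`. Cause columns
#' are summed away (hazards are all-cause). Values outside `[0, 1]` are
#' clipped with a warning.
#'
#' @param deaths Count tibble (any strata; a `cause` column is aggregated
#'   over).
#' @param population Count tibble on the same strata.
#' @param n Band width in years: 5 for adult five-year bands (including the
#'   open 85+ band), 1 for single ages of children.
#' @return Tibble of strata plus `hazard` and the intermediate `q`.
#' @export
mortality_hazard <- function(deaths, population, n) {
  if ("cause" %in% names(deaths)) {
    keys <- setdiff(names(deaths), c("cause", "count", "suppressed"))
    deaths <- deaths |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(count = sum(count), .groups = "drop")
  }
  keys <- intersect(setdiff(names(deaths), c("count", "suppressed")),
                    setdiff(names(population), c("count", "suppressed")))
  out <- population |>
    dplyr::select(dplyr::all_of(keys), count_p = count) |>
    dplyr::left_join(
      dplyr::select(deaths, dplyr::all_of(keys), count_d = count),
      by = keys
    ) |>
    dplyr::mutate(count_d = dplyr::coalesce(count_d, 0))
  if (any(out$count_p == 0)) {
    stop("estimation error: zero population in hazard stratum",
         call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(
      hazard = count_d / (n * count_p),
      q = count_d / (count_p + count_d / 2)
    )
  if (any(out$hazard > 1 | out$hazard < 0)) {
    warning("hazard outside [0, 1]; clipped")
    out$hazard <- pmin(pmax(out$hazard, 0), 1)
  }
  dplyr::select(out, dplyr::all_of(keys), hazard, q)
}

#' Complete a hazard table over a full stratum grid
#'
#' The opposite-sex hazard lookups in the double-loss corrections assume
#' the other parent occupies the same age band, which can reference
#' (band, sex) strata with no population (for example women in the open
#' 85+ band when no female cohort has reached it). Such strata carry no
#' decedents — the terms they multiply are essentially zero — but the
#' lookup still needs a value: each missing cell takes the hazard of the
#' nearest younger band with data in the same (year, sex, race) stratum,
#' and 0 when none exists.
#'
#' @param hazards Output of [mortality_hazard()].
#' @param years,bands,sexes,races Grid to complete over (defaults taken
#'   from the table itself, with `bands = adult_bands()`).
#' @return Hazard tibble covering the full grid.
#' @export
complete_hazards <- function(hazards, years = NULL, bands = adult_bands(),
                             sexes = NULL, races = NULL) {
  years <- years %||% unique(hazards$year)
  sexes <- sexes %||% unique(hazards$sex)
  races <- races %||% unique(hazards$race_ethnicity)
  grid <- tidyr::expand_grid(
    year = years, age_band = bands, sex = sexes, race_ethnicity = races
  )
  ord <- order(band_bounds(bands)$lo)
  grid |>
    dplyr::left_join(
      dplyr::select(hazards, year, age_band, sex, race_ethnicity, hazard),
      by = c("year", "age_band", "sex", "race_ethnicity")
    ) |>
    dplyr::mutate(age_band = factor(age_band, levels = bands[ord])) |>
    dplyr::arrange(year, sex, race_ethnicity, age_band) |>
    dplyr::group_by(year, sex, race_ethnicity) |>
    tidyr::fill(hazard, .direction = "down") |>
    dplyr::ungroup() |>
    dplyr::mutate(hazard = dplyr::coalesce(hazard, 0),
                  age_band = as.character(age_band))
}

# Hazard lookup helper: returns hazard for (year, band, sex, race) rows,
# 0 for bands whose lower bound is below the youngest tabulated band
# (lagged parental ages below 15), and optionally reuses the earliest
# tabulated year for years before coverage.
hazard_lookup <- function(hazards, keys, history_floor = TRUE) {
  y_min <- min(hazards$year)
  if (history_floor) {
    keys$year_lk <- pmax(keys$year, y_min)
  } else {
    if (any(keys$year < y_min)) {
      stop("estimation error: opposite-sex hazard history missing before ",
           y_min, call. = FALSE)
    }
    keys$year_lk <- keys$year
  }
  out <- keys |>
    dplyr::left_join(
      dplyr::select(hazards, year_lk = year, age_band, sex, race_ethnicity,
                    hazard),
      by = c("year_lk", "age_band", "sex", "race_ethnicity")
    )
  below <- band_bounds(out$age_band)$lo < min(band_bounds(hazards$age_band)$lo)
  out$hazard[is.na(out$hazard) & below] <- 0
  if (anyNA(out$hazard)) {
    stop("estimation error: opposite-sex hazard missing for required ",
         "stratum", call. = FALSE)
  }
  out$hazard
}

#' Incidence components: parental death, same-year and prior double loss
#'
#' For each (year, parental age band, parental sex, race/ethnicity, child
#' age, cause) stratum computes:
#' * `death_of_parent` — expected children times cause-specific deaths;
#' * `new_double` — children who also lose the opposite-sex parent (same
#'   band and race, any cause) in the same year, via the mid-band hazard;
#' * `previous` — children who already lost the opposite-sex parent in any
#'   of the previous `b - 1` years: for each lag `i` the five single-age
#'   lagged hazards of the band are averaged, the lag contributions summed
#'   and the cumulative prior-loss probability capped at 1.
#'
#' @param expected Band-level output of [expected_children()].
#' @param deaths Cause-mapped mortality tibble (real-valued counts allowed).
#' @param hazards Adult all-cause hazard table from [mortality_hazard()],
#'   covering the current year and (for `previous`) up to 16 prior years.
#' @param history_floor Reuse the earliest tabulated hazard year for lagged
#'   years before coverage (mirrors the constant-before-reference fertility
#'   assumption); if `FALSE`, missing history is an error.
#' @return Tibble with columns `year`, `age_band`, `sex`, `race_ethnicity`,
#'   `child_age`, `cause`, `death_of_parent`, `new_double`, `previous`.
#' @export
incidence_components <- function(expected, deaths, hazards,
                                 history_floor = TRUE) {
  comp <- deaths |>
    dplyr::inner_join(
      expected,
      by = c("year", "age_band", "sex", "race_ethnicity"),
      relationship = "many-to-many"
    ) |>
    dplyr::mutate(death_of_parent = expected_children * count)
  # same-year loss of the opposite-sex parent (same band, same race)
  comp$new_double <- comp$death_of_parent * hazard_lookup(
    hazards,
    tibble::tibble(
      year = comp$year, age_band = comp$age_band,
      sex = ifelse(comp$sex == "female", "male", "female"),
      race_ethnicity = comp$race_ethnicity
    ),
    history_floor
  )
  # prior-loss probability: mean over the band's single ages of the lagged
  # opposite-sex hazard, summed over lags 1..b-1, capped at 1
  band_tbl <- band_bounds(unique(comp$age_band))
  band_ages <- purrr::map2(band_tbl$lo, pmin(band_tbl$hi, 94), seq)
  names(band_ages) <- band_tbl$band
  lag_grid <- comp |>
    dplyr::distinct(year, age_band, sex, race_ethnicity) |>
    tidyr::expand_grid(i = seq_len(17)) |>
    dplyr::mutate(ages = band_ages[age_band]) |>
    tidyr::unnest_longer(ages, values_to = "a_single") |>
    dplyr::mutate(
      lag_band = band_for_age(.data$a_single - i, adult_bands()),
      lag_band = dplyr::coalesce(.data$lag_band, "0-14")
    )
  lag_grid$h <- hazard_lookup(
    hazards,
    tibble::tibble(
      year = lag_grid$year - lag_grid$i, age_band = lag_grid$lag_band,
      sex = ifelse(lag_grid$sex == "female", "male", "female"),
      race_ethnicity = lag_grid$race_ethnicity
    ),
    history_floor
  )
  lag_means <- lag_grid |>
    dplyr::group_by(year, age_band, sex, race_ethnicity, i) |>
    dplyr::summarise(h_mean = mean(.data$h), .groups = "drop") |>
    dplyr::arrange(i) |>
    dplyr::group_by(year, age_band, sex, race_ethnicity) |>
    dplyr::mutate(cum_prob = pmin(cumsum(.data$h_mean), 1)) |>
    dplyr::ungroup() |>
    # cum_prob at lag index i covers lags 1..i; a child aged b has prior
    # years 1..b-1, so join on i = b - 1
    dplyr::mutate(child_age = i + 1) |>
    dplyr::select(year, age_band, sex, race_ethnicity, child_age, cum_prob)
  comp |>
    dplyr::left_join(
      lag_means,
      by = c("year", "age_band", "sex", "race_ethnicity", "child_age")
    ) |>
    dplyr::mutate(
      prev_prob = ifelse(child_age <= 1, 0,
                         dplyr::coalesce(.data$cum_prob, 0)),
      previous = prev_prob * death_of_parent
    ) |>
    dplyr::select(year, age_band, sex, race_ethnicity, child_age, cause,
                  death_of_parent, new_double, previous)
}

#' Combine maternal and paternal components into de-duplicated incidence
#'
#' New orphanhood in a stratum is the sum of the maternal and paternal
#' parental-death terms, minus the average of the two same-year
#' double-loss terms (they estimate the same children from either side),
#' minus both prior-loss terms. Negative corrected values are floored at 0
#' with a warning.
#'
#' @param components Output of [incidence_components()] containing both
#'   sexes.
#' @return Tibble `year`, `age_band`, `race_ethnicity`, `child_age`,
#'   `cause`, `new`.
#' @seealso [incidence_by_sex()] for the by-parental-sex decomposition.
#' @export
combine_incidence <- function(components) {
  wide <- components |>
    tidyr::pivot_wider(
      id_cols = c(year, age_band, race_ethnicity, child_age, cause),
      names_from = sex,
      values_from = c(death_of_parent, new_double, previous),
      values_fill = 0
    )
  for (col in c("death_of_parent_female", "death_of_parent_male",
                "new_double_female", "new_double_male",
                "previous_female", "previous_male")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide <- wide |>
    dplyr::mutate(
      new = .data$death_of_parent_female + .data$death_of_parent_male -
        (.data$new_double_female + .data$new_double_male) / 2 -
        .data$previous_female - .data$previous_male
    )
  if (any(wide$new < 0)) {
    warning(sum(wide$new < 0),
            " corrected incidence value(s) below 0; floored at 0")
    wide$new <- pmax(wide$new, 0)
  }
  dplyr::select(wide, year, age_band, race_ethnicity, child_age, cause, new)
}

#' Incidence by sex of deceased parent
#'
#' Maternal and paternal incidence each count children experiencing the
#' death of that parent (including children who lose both), net of
#' children who had already lost that parent's partner in prior years:
#' the band sum of `death_of_parent - previous`.
#'
#' @param components Output of [incidence_components()].
#' @param keep_band Keep the parental age-band stratification (needed for
#'   the grandparent age-composition weights); if `FALSE` bands are summed.
#' @return Tibble `year`, (`age_band`,) `sex`, `race_ethnicity`,
#'   `child_age`, `cause`, `new`.
#' @export
incidence_by_sex <- function(components, keep_band = FALSE) {
  grp <- c("year", if (keep_band) "age_band", "sex", "race_ethnicity",
           "child_age", "cause")
  components |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(new = sum(death_of_parent - previous),
                     .groups = "drop")
}

# Cohort accrual with child-survival discounting shared by the orphanhood
# and caregiver prevalence calculations. start_j = 1 omits the current
# cohort-year factor (incidence already conditions on survival to the end
# of the loss year); start_j = 0 includes it (cross-sectional caregiver
# contributions).
cohort_accumulate <- function(inc, child_hazards, years, start_j,
                              value_col = "new", out_col = "lifetime") {
  grp <- setdiff(names(inc), c("year", "child_age", value_col))
  have_years <- unique(inc$year)
  h_keys <- intersect(c("year", "race_ethnicity", "age"),
                      names(child_hazards))
  hl <- dplyr::select(child_hazards, dplyr::all_of(h_keys), hazard)
  purrr::map_dfr(years, function(y) {
    need <- seq(y - 17, y)
    if (!all(need %in% have_years)) {
      stop("estimation error: incidence history incomplete for year ", y,
           " (need ", y - 17, "-", y, ")", call. = FALSE)
    }
    acc <- NULL
    for (i in 0:17) {
      cohort <- inc |>
        dplyr::filter(year == y - i, child_age + i <= 17) |>
        dplyr::mutate(child_age = child_age + i, lag = i)
      if (!nrow(cohort)) next
      # survival product over the j factors
      j_seq <- function(ii) if (ii == 0) {
        if (start_j == 0) 0 else integer(0)
      } else {
        seq(start_j, ii)
      }
      js <- j_seq(i)
      if (length(js)) {
        sv <- rep(1, nrow(cohort))
        for (j in js) {
          kk <- tibble::tibble(year = y - j, age = cohort$child_age - j)
          if ("race_ethnicity" %in% h_keys) {
            kk$race_ethnicity <- cohort$race_ethnicity
          }
          hj <- dplyr::left_join(kk, hl, by = names(kk))$hazard
          if (anyNA(hj)) {
            stop("estimation error: child hazard missing for year ", y - j,
                 call. = FALSE)
          }
          sv <- sv * (1 - hj)
        }
        cohort$contrib <- cohort[[value_col]] * sv
      } else {
        cohort$contrib <- cohort[[value_col]]
      }
      acc <- dplyr::bind_rows(acc, cohort)
    }
    acc |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "child_age")))) |>
      dplyr::summarise(!!out_col := sum(.data$contrib), .groups = "drop") |>
      dplyr::mutate(year = y, .before = 1)
  })
}

#' Survival-adjusted orphanhood prevalence
#'
#' Prevalence in year `y` at child age `b` accrues the children who newly
#' experienced orphanhood at age `b - i` in year `y - i` for `i = 0..b`,
#' discounted by the probability of the child surviving the intervening
#' years (product over `j = 1..i` of one minus the single-age child
#' hazard); children who would have turned 18 are excluded by
#' construction. Requires a complete 17-year incidence history before each
#' requested year.
#'
#' @param incidence Tibble of new-orphanhood counts with columns `year`,
#'   `child_age`, grouping columns (e.g. `race_ethnicity`, `cause`,
#'   optionally `sex`) and `new`. Parental age bands should be summed away
#'   first.
#' @param child_hazards Single-age child hazard tibble (`year`, `age`,
#'   optionally `race_ethnicity`, `hazard`) from [mortality_hazard()] with
#'   `n = 1`.
#' @param years Years for which to report prevalence.
#' @return Tibble of the grouping columns plus `year`, `child_age`,
#'   `lifetime`.
#' @export
accumulate_prevalence <- function(incidence, child_hazards, years) {
  cohort_accumulate(incidence, child_hazards, years, start_j = 1)
}
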