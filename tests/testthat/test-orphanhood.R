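test_that("mid-band hazard equals the life-table form to 1e-12", {
  set.seed(13)
  n_cases <- 200
  D <- runif(n_cases, 0, 1) * 10^runif(n_cases, 0, 4)
  P <- D + 10^runif(n_cases, 0.5, 6) # always P > D
  n <- sample(c(1, 5), n_cases, replace = TRUE)
  for (i in seq_len(n_cases)) {
    q <- D[i] / (P[i] + D[i] / 2)
    lhs <- (1 / n[i]) * 2 * q / (2 - q)
    rhs <- D[i] / (n[i] * P[i])
    expect_lt(abs(lhs - rhs) / rhs, 1e-12)
  }
})

test_that("mortality_hazard computes D/(nP), clips and errors as specified", {
  d <- tibble::tibble(year = 2000, age_band = "40-44", sex = "male",
                      race_ethnicity = "g", cause = c("a", "b"),
                      count = c(4, 6))
  p <- tibble::tibble(year = 2000, age_band = "40-44", sex = "male",
                      race_ethnicity = "g", count = 1000)
  got <- mortality_hazard(d, p, n = 5)
  expect_equal(got$hazard, 10 / 5000) # 0.002, causes summed
  expect_equal(got$q, 10 / (1000 + 5))

  d1 <- tibble::tibble(year = 2000, age = 3, race_ethnicity = "g",
                       count = 5)
  p1 <- tibble::tibble(year = 2000, age = 3, race_ethnicity = "g",
                       count = 500)
  expect_equal(mortality_hazard(d1, p1, n = 1)$hazard, 0.01)
  expect_equal(mortality_hazard(dplyr::mutate(d1, count = 0), p1, 1)$hazard,
               0)
  expect_error(mortality_hazard(d1, dplyr::mutate(p1, count = 0), 1),
               "zero population")
  expect_warning(
    over <- mortality_hazard(dplyr::mutate(d1, count = 1000), p1, 1),
    "clipped"
  )
  expect_equal(over$hazard, 1)
})

test_that("expected children multiply cohort fertility by pediatric survival", {
  fert <- tidyr::expand_grid(
    year = 1983:2000, age_band = mother_bands(), sex = "female",
    race_ethnicity = "g"
  ) |>
    dplyr::mutate(rate = dplyr::case_when(
      age_band == "15-19" ~ 0.05,
      age_band == "20-24" ~ 0.2,
      age_band == "25-29" ~ 0.1,
      TRUE ~ 0
    ))
  surv <- tidyr::expand_grid(birth_year = 1983:2000, age = 0:17) |>
    dplyr::mutate(p_survive = 0.99)
  ec <- expected_children(fert, surv, years = 2000)
  lk <- function(band, b) {
    ec$expected_children[ec$age_band == band & ec$child_age == b]
  }
  # all of band 20-24 at b = 0 uses the 20-24 rate
  expect_equal(lk("20-24", 0), 0.2 * 0.99)
  # band 25-29 at b = 2: ages at birth 23..27 straddle two bands,
  # a - b = 23 resolves to the 20-24 rate
  expect_equal(lk("25-29", 2), mean(c(0.2, 0.2, 0.1, 0.1, 0.1)) * 0.99)
  # a - b below 15 contributes zero
  expect_equal(lk("20-24", 10), 0)
  # missing survival cohort is an estimation error
  expect_error(expected_children(fert, dplyr::filter(surv, birth_year > 1990),
                                 years = 2000),
               "child survival")
})

test_that("incidence components evaluate the worked double-loss values", {
  years <- 2000
  expected <- tidyr::expand_grid(
    year = years, age_band = "30-34", sex = c("female", "male"),
    race_ethnicity = "g", child_age = 0:17
  ) |> dplyr::mutate(expected_children = 0.5)
  deaths <- tibble::tibble(
    year = years, age_band = "30-34", sex = c("female", "male"),
    race_ethnicity = "g", cause = "all", count = 200
  )
  hz <- tidyr::expand_grid(
    year = 1984:2000, age_band = adult_bands(),
    sex = c("female", "male"), race_ethnicity = "g"
  ) |> dplyr::mutate(hazard = 0.002)
  comp <- incidence_components(expected, deaths, hz)
  f0 <- dplyr::filter(comp, sex == "female", child_age == 0)
  expect_equal(f0$death_of_parent, 100) # C x D
  expect_equal(f0$new_double, 0.2)      # h x C x D
  expect_equal(f0$previous, 0)          # no prior years at b = 0
  f5 <- dplyr::filter(comp, sex == "female", child_age == 5)
  # four lags of the band-mean lagged hazard, all 0.002
  expect_equal(f5$previous, 100 * 4 * 0.002)

  # degenerate: all-zero hazards kill both corrections
  hz0 <- dplyr::mutate(hz, hazard = 0)
  comp0 <- incidence_components(expected, deaths, hz0)
  expect_true(all(comp0$new_double == 0))
  expect_true(all(comp0$previous == 0))
})

test_that("combining sexes subtracts the averaged double and both previous terms", {
  comp <- tidyr::expand_grid(
    year = 2000, age_band = "30-34", sex = c("female", "male"),
    race_ethnicity = "g", child_age = 3, cause = "all"
  ) |>
    dplyr::mutate(
      death_of_parent = 100,
      new_double = c(0.4, 0.2),
      previous = c(1, 0)
    )
  new <- combine_incidence(comp)
  expect_equal(new$new, 100 + 100 - (0.4 + 0.2) / 2 - 1 - 0)
  bysex <- incidence_by_sex(comp)
  expect_equal(bysex$new[bysex$sex == "female"], 99) # dop - previous
  expect_equal(bysex$new[bysex$sex == "male"], 100)
  # zero corrections: plain sum of the parental-death terms
  comp0 <- dplyr::mutate(comp, new_double = 0, previous = 0)
  expect_equal(combine_incidence(comp0)$new, 200)
  # negative corrected incidence floors at zero with a warning
  compn <- dplyr::mutate(comp, previous = c(150, 100))
  expect_warning(floored <- combine_incidence(compn), "floored")
  expect_equal(floored$new, 0)
})

test_that("by-sex and combined incidence agree up to half the double-loss terms", {
  set.seed(23)
  comp <- tidyr::expand_grid(
    year = 2000:2001, age_band = c("30-34", "45-49"),
    sex = c("female", "male"), race_ethnicity = c("a", "b"),
    child_age = 0:17, cause = c("c1", "c2")
  ) |>
    dplyr::mutate(
      death_of_parent = runif(dplyr::n(), 10, 100),
      new_double = death_of_parent * runif(dplyr::n(), 0, 0.01),
      previous = death_of_parent * runif(dplyr::n(), 0, 0.02)
    )
  new <- combine_incidence(comp) |>
    dplyr::group_by(year, race_ethnicity, child_age, cause) |>
    dplyr::summarise(new = sum(new), .groups = "drop")
  bysex <- incidence_by_sex(comp) |>
    dplyr::group_by(year, race_ethnicity, child_age, cause) |>
    dplyr::summarise(new = sum(new), .groups = "drop")
  dd <- comp |>
    dplyr::group_by(year, race_ethnicity, child_age, cause) |>
    dplyr::summarise(half_dd = sum(new_double) / 2, .groups = "drop")
  gap <- dplyr::inner_join(bysex, new,
                           by = c("year", "race_ethnicity", "child_age",
                                  "cause"),
                           suffix = c("_s", "_c")) |>
    dplyr::inner_join(dd, by = c("year", "race_ethnicity", "child_age",
                                 "cause"))
  expect_equal(gap$new_s - gap$new_c, gap$half_dd)
})

test_that("prevalence accrual discounts by child survival with the j=1 start", {
  years_all <- 1985:2002
  inc <- tidyr::expand_grid(year = years_all, race_ethnicity = "g",
                            child_age = 0:17, cause = "all") |>
    dplyr::mutate(new = ifelse(year == 2000 & child_age == 0, 100, 0))
  chz <- tidyr::expand_grid(year = years_all, age = 0:17,
                            race_ethnicity = "g") |>
    dplyr::mutate(hazard = 0.01)
  got <- accumulate_prevalence(inc, chz, years = 2002)
  expect_equal(got$lifetime[got$child_age == 2], 100 * 0.99^2)
  expect_equal(sum(got$lifetime), 100 * 0.99^2)

  # hazard 1 everywhere: only the current year's incidence survives
  chz1 <- dplyr::mutate(chz, hazard = 1)
  inc1 <- dplyr::mutate(inc, new = 50)
  got1 <- accumulate_prevalence(inc1, chz1, years = 2002)
  expect_equal(sum(got1$lifetime), sum(50 * 18))

  # incomplete 17-year history is an estimation error
  expect_error(
    accumulate_prevalence(dplyr::filter(inc, year >= 1990), chz, 2002),
    "history incomplete"
  )
})

test_that("with zero child mortality prevalence telescopes across years", {
  set.seed(31)
  years_all <- 1980:2005
  inc <- tidyr::expand_grid(year = years_all, race_ethnicity = "g",
                            child_age = 0:17, cause = "all") |>
    dplyr::mutate(new = runif(dplyr::n(), 0, 10))
  chz <- tidyr::expand_grid(year = years_all, age = 0:17,
                            race_ethnicity = "g") |>
    dplyr::mutate(hazard = 0)
  prev <- accumulate_prevalence(inc, chz, years = 2004:2005)
  tot <- function(y) sum(prev$lifetime[prev$year == y])
  aged_out <- sum(prev$lifetime[prev$year == 2004 & prev$child_age == 17])
  new_y <- sum(inc$new[inc$year == 2005])
  expect_equal(tot(2005), tot(2004) - aged_out + new_y)
})

test_that("hazard completion fills empty strata from the nearest younger band", {
  hz <- tibble::tibble(
    year = 2000, age_band = c("15-19", "20-24"),
    sex = "female", race_ethnicity = "g", hazard = c(0.001, 0.002)
  )
  full <- complete_hazards(hz, years = 2000, sexes = "female", races = "g")
  expect_equal(nrow(full), length(adult_bands()))
  expect_equal(full$hazard[full$age_band == "85+"], 0.002)
  expect_equal(full$hazard[full$age_band == "15-19"], 0.001)
})
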