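acs_row <- function(year = 2010, gamma = 0.04, p_r = 0.5, p_mr = 0.2,
                    q_sg = 0.3) {
  tibble::tibble(
    year = year, sex = "female", race_ethnicity = "g",
    gamma_coreside = gamma, p_coreside_race = p_r,
    p_most_responsible = p_mr, q_skip_gen = q_sg
  )
}

test_that("caregiver proportions multiply out and partition gamma * p_r", {
  got <- caregiver_proportions(acs_row())
  expect_equal(got$gamma_skip_gen, 0.04 * 0.5 * 0.2 * 0.3) # 0.0012
  expect_equal(got$gamma_mr_not_sg, 0.04 * 0.5 * 0.2 * 0.7)
  expect_equal(got$gamma_co_not_mr, 0.04 * 0.5 * 0.8)
  # the three types partition gamma * p_r exactly (p*q + p(1-q) + (1-p) = 1)
  expect_equal(got$gamma_skip_gen + got$gamma_mr_not_sg +
                 got$gamma_co_not_mr, 0.04 * 0.5)
  expect_error(caregiver_proportions(acs_row(gamma = 1.2)),
               "configuration error")
})

test_that("years before the first surveyed year reuse its proportions", {
  acs <- dplyr::bind_rows(acs_row(2010), acs_row(2015, gamma = 0.05))
  got <- caregiver_proportions(acs, years = c(2005, 2010, 2015))
  expect_equal(got$gamma_coreside[got$year == 2005],
               got$gamma_coreside[got$year == 2010])
  expect_equal(got$gamma_coreside[got$year == 2015], 0.05)
})

test_that("grandparent incidence is gamma times deaths 30+ with primary split", {
  props <- caregiver_proportions(acs_row(2010, gamma = 0.04))
  deaths <- tibble::tibble(
    year = 2010, age_band = c("25-29", "30-34", "60-64"), sex = "female",
    race_ethnicity = "g", cause = "all", count = c(500, 4000, 6000)
  )
  g <- grandparent_incidence(props, deaths)
  # ages below 30 are excluded: total deaths 10,000
  sg <- g$g_loss[g$caregiver_type == "skip_gen"]
  expect_equal(sg, 0.0012 * 10000) # 12
  expect_equal(sum(g$g_loss[g$category == "primary"]),
               (0.0012 + 0.0028) * 10000)
  expect_equal(sum(g$g_loss[g$category == "secondary"]), 0.016 * 10000)
  # degenerate proportion
  props0 <- caregiver_proportions(acs_row(gamma = 0))
  expect_equal(sum(grandparent_incidence(props0, deaths)$g_loss), 0)
  expect_error(
    grandparent_incidence(props, dplyr::filter(deaths, age_band == "25-29")),
    "no age bands at 30"
  )
})

test_that("child-age disaggregation conserves totals in every mode", {
  props <- caregiver_proportions(acs_row())
  deaths <- tibble::tibble(year = 2010, age_band = "60-64", sex = "female",
                           race_ethnicity = "g", cause = "all",
                           count = 1000)
  g <- grandparent_incidence(props, deaths)
  # uniform composition: G/18 per age
  comp_u <- tidyr::expand_grid(
    year = 2010, age_band = c("35-39", "60-64"), sex = "female",
    race_ethnicity = "g", child_age = 0:17, cause = "all"
  ) |> dplyr::mutate(new = 2)
  got_u <- disaggregate_child_age(g, comp_u)
  flat <- got_u |>
    dplyr::group_by(caregiver_type) |>
    dplyr::summarise(spread = diff(range(g_loss)), n_ages = dplyr::n())
  expect_equal(flat$spread, rep(0, 3)) # G/18 per age within each type
  expect_equal(flat$n_ages, rep(18L, 3))
  expect_equal(
    got_u |> dplyr::group_by(caregiver_type) |>
      dplyr::summarise(s = sum(g_loss)) |> dplyr::pull(s),
    g$g_loss[order(g$caregiver_type)],
    tolerance = 1e-12
  )
  # point mass at age 17
  comp_p <- dplyr::mutate(comp_u, new = ifelse(child_age == 17, 5, 0))
  got_p <- disaggregate_child_age(g, comp_p)
  expect_equal(sum(got_p$g_loss[got_p$child_age != 17]), 0)
  expect_equal(sum(got_p$g_loss[got_p$child_age == 17]), sum(g$g_loss))
  # all-zero composition falls back to uniform with a warning
  comp_0 <- dplyr::mutate(comp_u, new = 0)
  expect_warning(got_0 <- disaggregate_child_age(g, comp_0), "uniform")
  expect_equal(got_0$g_loss, got_u$g_loss)
  # all_cause mode pools the numerator across causes before weighting
  comp_c <- dplyr::bind_rows(
    dplyr::mutate(comp_u, cause = "c1",
                  new = ifelse(child_age == 0, 10, 0)),
    dplyr::mutate(comp_u, cause = "c2",
                  new = ifelse(child_age == 1, 30, 0))
  )
  g2 <- dplyr::mutate(g, cause = "c1")
  got_c <- disaggregate_child_age(g2, comp_c, mode = "all_cause")
  w0 <- sum(got_c$g_loss[got_c$child_age == 0]) / sum(got_c$g_loss)
  expect_equal(w0, 0.25) # 10 / (10 + 30), pooled over causes
})

test_that("de-duplication reproduces the worked value and its limits", {
  g <- tibble::tibble(
    year = 2010, sex = "female", race_ethnicity = "g", cause = "all",
    caregiver_type = c("skip_gen", "most_responsible_not_sg",
                       "co_reside_not_mr"),
    g_loss = c(100, 0, 0)
  )
  hz <- tidyr::expand_grid(year = 2010, race_ethnicity = "g",
                           sex = c("female", "male")) |>
    dplyr::mutate(hazard = 0.01)
  got <- dedup_caregiver(g, dedup_params(), hz)
  # 100 * (1 - 0.11) * (1 - (0.01 + 0.01 - 1e-4) * 6/12) = 88.11445
  expect_equal(got$g_dedup, 88.11445, tolerance = 1e-9)
  # defaults carry the documented values
  p <- dedup_params()
  expect_equal(p$p_skip_gen_parent_died, 0.11)
  expect_equal(p$p_other_parent_died, 0.11)
  expect_equal(p$p_both_parents_present, 0.70)
  expect_equal(p$exposure_fraction, 0.5)
  # all dedup probabilities and hazards zero: identity on the total
  g_all <- dplyr::mutate(g, g_loss = c(100, 50, 25))
  hz0 <- dplyr::mutate(hz, hazard = 0)
  p0 <- dedup_params(0, 0, 1, 0)
  expect_equal(dedup_caregiver(g_all, p0, hz0)$g_dedup, 175)
  # orphan incidence is added for the combined loss
  orphan <- tibble::tibble(year = 2010, sex = "female",
                           race_ethnicity = "g", cause = "all", new = 10)
  got_l <- dedup_caregiver(g, dedup_params(), hz, orphan_new = orphan)
  expect_equal(got_l$l_new, got_l$g_dedup + 10)
})

test_that("de-duplication is strictly monotone in probabilities and hazards", {
  g <- tibble::tibble(
    year = 2010, sex = "female", race_ethnicity = "g", cause = "all",
    caregiver_type = c("skip_gen", "most_responsible_not_sg",
                       "co_reside_not_mr"),
    g_loss = c(100, 60, 40)
  )
  hz <- function(h) {
    tidyr::expand_grid(year = 2010, race_ethnicity = "g",
                       sex = c("female", "male")) |>
      dplyr::mutate(hazard = h)
  }
  base <- dedup_caregiver(g, dedup_params(), hz(0.01))$g_dedup
  expect_lt(dedup_caregiver(g, dedup_params(p_skip_gen_parent_died = 0.2),
                            hz(0.01))$g_dedup, base)
  expect_lt(dedup_caregiver(g, dedup_params(p_other_parent_died = 0.2),
                            hz(0.01))$g_dedup, base)
  expect_lt(dedup_caregiver(g, dedup_params(p_both_parents_present = 0.5),
                            hz(0.01))$g_dedup, base)
  expect_lt(dedup_caregiver(g, dedup_params(), hz(0.05))$g_dedup, base)
})

test_that("caregiver prevalence starts the survival product at lag 0", {
  years_all <- 1985:2002
  orphan_lt <- tibble::tibble(year = 2002, sex = "female",
                              race_ethnicity = "g", cause = "all",
                              child_age = 0, lifetime = 7)
  gd <- tidyr::expand_grid(year = years_all, sex = "female",
                           race_ethnicity = "g", cause = "all",
                           child_age = 0:17) |>
    dplyr::mutate(g_dedup = ifelse(year == 2002 & child_age == 0, 100, 0))
  chz <- tidyr::expand_grid(year = years_all, age = 0:17,
                            race_ethnicity = "g") |>
    dplyr::mutate(hazard = 0.01)
  got <- caregiver_prevalence(orphan_lt, gd, chz, years = 2002)
  at0 <- dplyr::filter(got, child_age == 0)
  # unlike the orphanhood accrual, the current year's factor applies
  expect_equal(at0$g_lifetime, 100 * 0.99)
  expect_equal(at0$l_lifetime, 7 + 100 * 0.99)
  # zero grandparent loss: combined prevalence equals orphanhood
  got0 <- caregiver_prevalence(orphan_lt,
                               dplyr::mutate(gd, g_dedup = 0), chz, 2002)
  expect_equal(dplyr::filter(got0, child_age == 0)$l_lifetime, 7)
  # zero child hazards: plain cumulative sum of contributions
  gd2 <- dplyr::mutate(gd, g_dedup = ifelse(child_age == 0, 10, 0))
  got2 <- caregiver_prevalence(orphan_lt, gd2,
                               dplyr::mutate(chz, hazard = 0), 2002)
  expect_equal(sum(got2$g_lifetime), 10 * 18)
})

test_that("parent hazard aggregation is a checked weighted mean", {
  rates <- tibble::tibble(age_band = c("30-34", "40-44"),
                          rate = c(0.01, 0.03))
  w <- tibble::tibble(age_band = c("30-34", "40-44"), weight = c(0.5, 0.5))
  expect_equal(parent_hazard_aggregate(rates, w)$hazard, 0.02)
  w1 <- tibble::tibble(age_band = "30-34", weight = 1)
  expect_equal(
    parent_hazard_aggregate(dplyr::filter(rates, age_band == "30-34"),
                            w1)$hazard, 0.01
  )
  expect_equal(
    parent_hazard_aggregate(dplyr::mutate(rates, rate = 0), w)$hazard, 0
  )
  expect_error(
    parent_hazard_aggregate(rates, dplyr::mutate(w, weight = c(0.5, 0.6))),
    "sum to 1"
  )
})
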