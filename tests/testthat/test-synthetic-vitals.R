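# Small-scale simulations keep this file fast; the full-scale oracle
# comparison lives in test-acceptance.R.

test_that("simulation is reproducible and validates its configuration", {
  cfg <- sim_config(n_families = 500, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$links, b$links)
  expect_identical(a$grandparent_roles, b$grandparent_roles)
  c2 <- simulate_cohort(sim_config(n_families = 500, seed = 43))
  expect_false(identical(a$individuals, c2$individuals))

  bad <- sim_config(n_families = 10)
  bad$mortality$hazard[1] <- 1.5
  expect_error(simulate_cohort(bad), "configuration error")
  expect_error(sim_config(grandparent_roles = c(skip_gen = 0.6,
                                                most_responsible = 0.3,
                                                housing_only = 0.2)),
               "sum > 1")
})

test_that("degenerate configurations behave as expected", {
  cfg0 <- sim_config(n_families = 300, seed = 1)
  cfg0$mortality$hazard <- rep(0, nrow(cfg0$mortality))
  cfg0$child_mortality$hazard <- rep(0, 18)
  ll0 <- simulate_cohort(cfg0)
  expect_true(all(is.na(ll0$individuals$death_year)))
  truth0 <- true_kin_loss(ll0)
  expect_equal(nrow(dplyr::filter(truth0, grepl("incidence", measure))), 0)

  cfgf <- sim_config(n_families = 300, seed = 1)
  cfgf$fertility$rate <- rep(0, nrow(cfgf$fertility))
  llf <- simulate_cohort(cfgf)
  expect_equal(sum(llf$individuals$role == "child"), 0)
})

test_that("emitted tables conserve events and validate against the schemas", {
  ll <- simulate_cohort(sim_config(n_families = 3000, seed = 8))
  tabs <- emit_vital_tables(ll)
  parents <- dplyr::filter(ll$individuals, role %in% c("mother", "father"))
  expect_equal(sum(tabs$mortality$count),
               sum(!is.na(parents$death_year)))
  children <- dplyr::filter(ll$individuals, role == "child")
  expect_equal(sum(tabs$natality$count[tabs$natality$sex == "female"]),
               nrow(children))
  expect_equal(sum(tabs$natality$count[tabs$natality$sex == "male"]),
               nrow(children))
  expect_equal(sum(tabs$child_mortality$count),
               sum(!is.na(children$death_year)))
  for (kind in c("mortality", "natality", "population", "child_mortality",
                 "child_population", "child_survival",
                 "caregiver_proportions")) {
    expect_silent(validate_vital_table(tabs[[kind]], kind))
  }
})

test_that("emitted fertility and co-residence proportions recover the configuration", {
  cfg <- sim_config(n_families = 100000, seed = 3)
  ll <- simulate_cohort(cfg)
  tabs <- emit_vital_tables(ll)
  fr <- compute_fertility(tabs$natality, tabs$population) |>
    dplyr::filter(sex == "female") |>
    dplyr::inner_join(cfg$fertility, by = "age_band",
                      suffix = c("", "_cfg")) |>
    dplyr::inner_join(cfg$races, by = "race_ethnicity") |>
    # prime reproductive bands: low-rate bands are noise-dominated and
    # young bands carry a partner-availability factor (births require a
    # living father aged 15-77), so realized rates sit slightly below
    # the schedule there by design
    dplyr::filter(age_band %in% c("25-29", "30-34", "35-39")) |>
    dplyr::group_by(age_band, race_ethnicity) |>
    dplyr::summarise(
      rate = mean(rate),
      expected = mean(rate_cfg * fertility_multiplier),
      .groups = "drop"
    )
  expect_lt(max(abs(fr$rate - fr$expected) / fr$expected), 0.08)

  cp <- tabs$caregiver_proportions
  pr <- cfg$grandparent_roles
  # p_most_responsible ~ (sg + mr) / (sg + mr + housing), q_sg ~ sg / (sg + mr)
  expect_equal(mean(cp$p_most_responsible),
               (pr[["skip_gen"]] + pr[["most_responsible"]]) / sum(pr),
               tolerance = 0.05)
  expect_equal(mean(cp$q_skip_gen),
               pr[["skip_gen"]] / (pr[["skip_gen"]] +
                                     pr[["most_responsible"]]),
               tolerance = 0.05)
  # race shares of co-residers track the configured race mix
  pr_race <- cp |>
    dplyr::distinct(year, race_ethnicity, p_coreside_race) |>
    dplyr::group_by(race_ethnicity) |>
    dplyr::summarise(p = mean(p_coreside_race))
  expect_equal(pr_race$p[pr_race$race_ethnicity == "groupA"], 0.7,
               tolerance = 0.05)
})

test_that("hand-built line lists give the exact kin-loss truth", {
  # mother dies when the child is 3: one maternal incident that year,
  # child prevalent each later year until turning 18
  ll <- manual_linelist(m_death = 2003, child_birth = 2000)
  tr <- true_kin_loss(ll)
  inc <- dplyr::filter(tr, measure == "incidence_combined")
  expect_equal(inc$year, 2003)
  expect_equal(inc$child_age, 3)
  expect_equal(inc$count, 1)
  prev_years <- dplyr::filter(tr, measure == "prevalence_combined")$year
  expect_equal(sort(prev_years), 2003:2017) # drops out at age 18
  mat <- dplyr::filter(tr, measure == "incidence_maternal")
  expect_equal(mat$cause, "heart_disease")

  # both parents die the same year: combined incidence 1, not 2
  ll2 <- manual_linelist(m_death = 2005, f_death = 2005)
  tr2 <- true_kin_loss(ll2)
  expect_equal(sum(dplyr::filter(tr2,
                                 measure == "incidence_combined")$count), 1)
  expect_equal(sum(dplyr::filter(tr2,
                                 measure == "incidence_maternal")$count), 1)
  expect_equal(sum(dplyr::filter(tr2,
                                 measure == "incidence_paternal")$count), 1)

  # parents die in different years: still one combined loss, at the first
  ll3 <- manual_linelist(m_death = 2008, f_death = 2004)
  tr3 <- true_kin_loss(ll3)
  inc3 <- dplyr::filter(tr3, measure == "incidence_combined")
  expect_equal(inc3$year, 2004)
  expect_equal(sum(inc3$count), 1)

  # child dies in the year of parental death: incident that year, never
  # prevalent afterwards
  ll4 <- manual_linelist(m_death = 2006, child_death = 2006)
  tr4 <- true_kin_loss(ll4)
  expect_equal(dplyr::filter(tr4, measure == "incidence_combined")$year,
               2006)
  expect_equal(nrow(dplyr::filter(tr4, measure == "prevalence_combined",
                                  year > 2006)), 0)

  # caregiving grandparent death: one grandchild counted, de-duplicated
  # against orphanhood in the combined caregiver measure
  ll5 <- manual_linelist(m_death = 2010, gm_death = 2005,
                         gp_role = "skip_gen")
  tr5 <- true_kin_loss(ll5)
  expect_equal(dplyr::filter(tr5, measure == "gp_incidence_primary")$year,
               2005)
  cg <- dplyr::filter(tr5, measure == "caregiver_incidence_combined")
  expect_equal(cg$year, 2005) # first loss of any caregiver
  expect_equal(sum(cg$count), 1)

  # dangling link ids are an integrity error
  ll_bad <- manual_linelist(m_death = 2003)
  ll_bad$links$mother_id <- 99L
  expect_error(true_kin_loss(ll_bad), "integrity error")
})

test_that("truth prevalence satisfies the stock-flow identity", {
  ll <- simulate_cohort(sim_config(n_families = 5000, seed = 21))
  tr <- true_kin_loss(ll)
  # prevalence(y) = prevalence(y-1) + incidence(y) - aged out - died;
  # with exact enumeration the identity reduces to: every prevalent child
  # in year y either was prevalent in y-1 or is incident in y
  prev <- tr |>
    dplyr::filter(measure == "prevalence_combined") |>
    dplyr::group_by(year) |>
    dplyr::summarise(prev = sum(count))
  inc <- tr |>
    dplyr::filter(measure == "incidence_combined") |>
    dplyr::group_by(year) |>
    dplyr::summarise(inc = sum(count))
  x <- tibble::tibble(year = min(ll$years):max(ll$years)) |>
    dplyr::left_join(prev, by = "year") |>
    dplyr::left_join(inc, by = "year") |>
    dplyr::mutate(prev = dplyr::coalesce(prev, 0),
                  inc = dplyr::coalesce(inc, 0))
  # stock never exceeds last year's stock plus this year's flow
  gap <- x$prev[-1] - (x$prev[-nrow(x)] + x$inc[-1])
  expect_true(all(gap <= 0))
})

test_that("dampened-fertility coupling lowers realized births near deaths", {
  base <- sim_config(n_families = 30000, seed = 14)
  damp <- sim_config(n_families = 30000, seed = 14,
                     fertility_coupling = list(scenario = "zero_at_death",
                                               onset = 3, scale = 0.5))
  ll_b <- simulate_cohort(base)
  ll_d <- simulate_cohort(damp)
  n_b <- sum(ll_b$individuals$role == "child")
  n_d <- sum(ll_d$individuals$role == "child")
  expect_lt(n_d, n_b)
  # births within 3 years of a parent's death are rarer under coupling
  frac_near_death <- function(ll) {
    ind <- ll$individuals
    links <- ll$links
    cb <- ind$birth_year[match(links$child_id, ind$id)]
    md <- ind$death_year[match(links$mother_id, ind$id)]
    near <- !is.na(md) & (md - cb) >= 0 & (md - cb) <= 2
    mean(near)
  }
  expect_lt(frac_near_death(ll_d), frac_near_death(ll_b))
})
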