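#' Exact kin-loss truth from a simulated line list
#'
#' Brute-force enumeration of the estimand over the family line list: for
#' every child, the years in which each parent (and any caregiving
#' grandparent) died while the child was aged 0-17 and still alive that
#' year. A child orphaned by both parents — in the same year or in
#' different years — counts exactly once in combined incidence, in the
#' year of the first qualifying parental death. Prevalence in year `y`
#' counts living children aged 0-17 at the end of `y` who ever
#' experienced the loss; children who died or turned 18 drop out, so
#' `prevalence(y) = prevalence(y-1) + incidence(y) - aged_out - died`
#' holds exactly by construction.
#'
#' Maternal (paternal) incidence counts every child experiencing the death
#' of the mother (father), including children who lose both parents, with
#' the cause of that parent's death. Grandparent caregiver loss counts one
#' grandchild (the youngest alive) per deceased caregiving grandparent
#' with at least one living grandchild under 18; primary loss covers the
#' skip-generation and most-responsible roles, secondary the housing-only
#' role.
#'
#' @param linelist A `kinloss_linelist` from [simulate_cohort()].
#' @param years Years to tabulate; defaults to the simulated years.
#' @return Tibble `year`, `measure`, `race_ethnicity`, `child_age`,
#'   `cause`, `count` with measures `incidence_combined`,
#'   `incidence_maternal`, `incidence_paternal`, `prevalence_combined`,
#'   `prevalence_maternal`, `prevalence_paternal`,
#'   `gp_incidence_primary`, `gp_incidence_secondary`,
#'   `caregiver_incidence_combined`, `caregiver_prevalence_combined`.
#'   `cause` is `"all"` for combined measures.
#' @export
true_kin_loss <- function(linelist, years = NULL) {
  stopifnot(inherits(linelist, "kinloss_linelist"))
  ind <- linelist$individuals
  links <- linelist$links
  if (is.null(years)) years <- linelist$years
  bad <- !c(links$child_id, links$mother_id, links$father_id) %in% ind$id
  if (any(bad)) {
    stop("integrity error: dangling link id(s) in line list", call. = FALSE)
  }
  if (!nrow(links)) {
    return(tibble::tibble(year = integer(), measure = character(),
                          race_ethnicity = character(),
                          child_age = integer(), cause = character(),
                          count = integer()))
  }
  idx <- function(ids) match(ids, ind$id)
  ch <- tibble::tibble(
    child_id = links$child_id,
    birth_year = ind$birth_year[idx(links$child_id)],
    death_year = ind$death_year[idx(links$child_id)],
    race_ethnicity = ind$race_ethnicity[idx(links$child_id)],
    m_death = ind$death_year[idx(links$mother_id)],
    m_cause = ind$cause[idx(links$mother_id)],
    f_death = ind$death_year[idx(links$father_id)],
    f_cause = ind$cause[idx(links$father_id)]
  )
  qualifies <- function(event_year) {
    !is.na(event_year) &
      event_year - ch$birth_year >= 0 &
      event_year - ch$birth_year <= 17 &
      (is.na(ch$death_year) | ch$death_year >= event_year)
  }
  ch$m_ok <- qualifies(ch$m_death)
  ch$f_ok <- qualifies(ch$f_death)
  ch$first_loss_year <- pmin(ifelse(ch$m_ok, ch$m_death, NA),
                             ifelse(ch$f_ok, ch$f_death, NA), na.rm = TRUE)
  ch$first_loss_year[!ch$m_ok & !ch$f_ok] <- NA

  alive_at <- function(y) is.na(ch$death_year) | ch$death_year > y
  age_ok_at <- function(y) {
    a <- y - ch$birth_year
    a >= 0 & a <= 17
  }

  tab <- function(sel, y, measure, cause = NULL) {
    if (!any(sel)) return(NULL)
    d <- tibble::tibble(
      race_ethnicity = ch$race_ethnicity[sel],
      child_age = y - ch$birth_year[sel],
      cause = if (is.null(cause)) "all" else cause[sel]
    )
    d |>
      dplyr::count(race_ethnicity, child_age, cause, name = "count") |>
      dplyr::mutate(year = y, measure = measure, .before = 1)
  }

  # grandparent caregiver losses: one (youngest living) grandchild per
  # deceased caregiving grandparent with a living under-18 grandchild
  gpr <- linelist$grandparent_roles
  gp_events <- NULL
  if (nrow(gpr)) {
    gp_events <- gpr |>
      dplyr::mutate(
        gp_death = ind$death_year[idx(grandparent_id)],
        gp_cause = ind$cause[idx(grandparent_id)],
        c_birth = ind$birth_year[idx(child_id)],
        c_death = ind$death_year[idx(child_id)],
        c_race = ind$race_ethnicity[idx(child_id)]
      ) |>
      dplyr::filter(
        !is.na(.data$gp_death),
        .data$gp_death - .data$c_birth >= 0,
        .data$gp_death - .data$c_birth <= 17,
        is.na(.data$c_death) | .data$c_death >= .data$gp_death
      ) |>
      dplyr::group_by(grandparent_id) |>
      dplyr::slice_max(.data$c_birth, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::mutate(category = ifelse(role == "housing_only",
                                      "secondary", "primary"))
  }

  out <- purrr::map_dfr(years, function(y) {
    res <- list(
      tab(ch$first_loss_year == y & !is.na(ch$first_loss_year), y,
          "incidence_combined"),
      tab(ch$m_ok & ch$m_death == y, y, "incidence_maternal", ch$m_cause),
      tab(ch$f_ok & ch$f_death == y, y, "incidence_paternal", ch$f_cause),
      tab(!is.na(ch$first_loss_year) & ch$first_loss_year <= y &
            alive_at(y) & age_ok_at(y), y, "prevalence_combined"),
      tab(ch$m_ok & ch$m_death <= y & alive_at(y) & age_ok_at(y), y,
          "prevalence_maternal", ch$m_cause),
      tab(ch$f_ok & ch$f_death <= y & alive_at(y) & age_ok_at(y), y,
          "prevalence_paternal", ch$f_cause)
    )
    if (!is.null(gp_events) && nrow(gp_events)) {
      for (cat in c("primary", "secondary")) {
        ev <- dplyr::filter(gp_events, category == cat, .data$gp_death == y)
        if (nrow(ev)) {
          res <- c(res, list(
            ev |>
              dplyr::count(race_ethnicity = .data$c_race,
                           child_age = y - .data$c_birth,
                           cause = .data$gp_cause, name = "count") |>
              dplyr::mutate(year = y,
                            measure = paste0("gp_incidence_", cat),
                            .before = 1)
          ))
        }
      }
      # combined caregiver loss: union of orphaned children and the
      # children attributed to grandparent caregiver deaths
      gp_first <- gp_events |>
        dplyr::group_by(child_id) |>
        dplyr::summarise(gp_year = min(.data$gp_death), .groups = "drop")
      cg <- ch |>
        dplyr::left_join(gp_first, by = "child_id") |>
        dplyr::mutate(
          cg_year = pmin(first_loss_year, .data$gp_year, na.rm = TRUE)
        )
      cg$cg_year[is.na(cg$first_loss_year) & is.na(cg$gp_year)] <- NA
      sel_i <- !is.na(cg$cg_year) & cg$cg_year == y
      sel_p <- !is.na(cg$cg_year) & cg$cg_year <= y & alive_at(y) &
        age_ok_at(y)
      res <- c(res, list(
        tab(sel_i, y, "caregiver_incidence_combined"),
        tab(sel_p, y, "caregiver_prevalence_combined")
      ))
    }
    dplyr::bind_rows(res)
  })
  template <- tibble::tibble(
    year = integer(), measure = character(), race_ethnicity = character(),
    child_age = integer(), cause = character(), count = integer()
  )
  dplyr::bind_rows(template, out)
}

#' Aggregate vital tables from a simulated line list
#'
#' Tabulates the line list into the count tables the estimation pipeline
#' consumes, keyed exactly as the loader schemas: adult mortality by
#' (year, five-year band, sex, race, cause); natality by (year, parental
#' band, parental sex, race) for both mothers and fathers (including the
#' male 55-77 band); end-of-year adult population by band, sex and race
#' (plus the male 55-77 band used for paternal fertility denominators);
#' child deaths and end-of-year child population by single age and race;
#' realized cohort survival (probability of surviving from birth through
#' each age); and realized caregiver co-residence proportions by year,
#' sex and race with binomial 90% margins of error.
#'
#' The mortality, natality and population tables describe the *parental
#' generation* — the closed study population whose births and deaths are
#' both tracked, so that the fertility-attribution identity underlying
#' the estimator holds exactly. The grandparent generation (whose own
#' parent-child links are outside the simulated window) enters only
#' through the co-residence proportions, which are measured against all
#' adults aged 30+.
#'
#' @param linelist A `kinloss_linelist`.
#' @return Named list of tibbles: `mortality`, `natality`, `population`,
#'   `child_mortality`, `child_population`, `child_survival`,
#'   `caregiver_proportions`.
#' @export
emit_vital_tables <- function(linelist) {
  stopifnot(inherits(linelist, "kinloss_linelist"))
  ind <- linelist$individuals
  links <- linelist$links
  years <- linelist$years
  adults <- dplyr::filter(ind, role %in% c("mother", "father"))
  children <- dplyr::filter(ind, role == "child")

  mortality <- adults |>
    dplyr::filter(!is.na(death_year)) |>
    dplyr::mutate(
      year = death_year,
      age_band = band_for_age(death_year - birth_year, adult_bands())
    ) |>
    dplyr::count(year, age_band, sex, race_ethnicity, cause,
                 name = "count")

  mother_ab <- ind$birth_year[match(links$mother_id, ind$id)]
  father_ab <- ind$birth_year[match(links$father_id, ind$id)]
  cb <- children$birth_year[match(links$child_id, children$id)]
  crace <- children$race_ethnicity[match(links$child_id, children$id)]
  natality <- dplyr::bind_rows(
    tibble::tibble(
      year = cb, sex = "female",
      age_band = band_for_age(cb - mother_ab, mother_bands()),
      race_ethnicity = crace
    ),
    tibble::tibble(
      year = cb, sex = "male",
      age_band = band_for_age(cb - father_ab, father_bands()),
      race_ethnicity = crace
    )
  ) |>
    dplyr::count(year, age_band, sex, race_ethnicity, name = "count")

  pop_year <- function(y) {
    a <- adults |>
      dplyr::filter(is.na(death_year) | death_year > y,
                    y - birth_year >= 15)
    age <- y - a$birth_year
    dplyr::bind_rows(
      tibble::tibble(year = y, age_band = band_for_age(age, adult_bands()),
                     sex = a$sex, race_ethnicity = a$race_ethnicity),
      tibble::tibble(year = y, age_band = "55-77", sex = a$sex,
                     race_ethnicity = a$race_ethnicity)[
                       a$sex == "male" & age >= 55 & age <= 77, ]
    ) |>
      dplyr::count(year, age_band, sex, race_ethnicity, name = "count")
  }
  population <- purrr::map_dfr(years, pop_year)

  child_mortality <- children |>
    dplyr::filter(!is.na(death_year)) |>
    dplyr::mutate(year = death_year, age = death_year - birth_year) |>
    dplyr::count(year, age, race_ethnicity, name = "count")
  child_population <- purrr::map_dfr(years, function(y) {
    children |>
      dplyr::filter(is.na(death_year) | death_year > y,
                    y - birth_year >= 0, y - birth_year <= 17) |>
      dplyr::mutate(year = y, age = y - birth_year) |>
      dplyr::count(year, age, race_ethnicity, name = "count")
  })

  y1 <- max(years)
  child_survival <- children |>
    dplyr::group_by(birth_year) |>
    dplyr::summarise(n_born = dplyr::n(),
                     deaths = list(death_year[!is.na(death_year)]),
                     .groups = "drop") |>
    dplyr::mutate(max_age = pmin(17, y1 - birth_year)) |>
    purrr::pmap_dfr(function(birth_year, n_born, deaths, max_age) {
      ages <- 0:max_age
      n_alive <- vapply(
        ages,
        function(b) n_born - sum(deaths <= birth_year + b),
        numeric(1)
      )
      tibble::tibble(birth_year = birth_year, age = ages,
                     p_survive = n_alive / n_born)
    })

  caregiver_proportions <- .emit_caregiver_props(linelist)

  list(mortality = mortality, natality = natality,
       population = population, child_mortality = child_mortality,
       child_population = child_population,
       child_survival = child_survival,
       caregiver_proportions = caregiver_proportions)
}

# realized co-residence proportions: a grandparent counts as co-residing
# in year y if alive at the end of y, aged 30+, holds a caregiver role
# and has a living grandchild under 18
.emit_caregiver_props <- function(linelist) {
  ind <- linelist$individuals
  gpr <- linelist$grandparent_roles
  years <- linelist$years
  if (!nrow(gpr)) {
    return(tibble::tibble(
      year = integer(), sex = character(), race_ethnicity = character(),
      gamma_coreside = numeric(), p_coreside_race = numeric(),
      p_most_responsible = numeric(), q_skip_gen = numeric(),
      moe90_gamma_coreside = numeric()
    ))
  }
  adults <- dplyr::filter(ind, role != "child")
  children <- dplyr::filter(ind, role == "child")
  gp_info <- gpr |>
    dplyr::distinct(grandparent_id, role) |>
    dplyr::left_join(
      dplyr::select(ind, grandparent_id = id, sex, race_ethnicity,
                    birth_year, death_year),
      by = "grandparent_id"
    )
  gc <- gpr |>
    dplyr::left_join(
      dplyr::select(children, child_id = id, c_birth = birth_year,
                    c_death = death_year),
      by = "child_id"
    )
  z90 <- moe90_to_sd_factor()
  purrr::map_dfr(years, function(y) {
    has_gc <- gc |>
      dplyr::filter(.data$c_birth <= y, y - .data$c_birth <= 17,
                    is.na(.data$c_death) | .data$c_death > y) |>
      dplyr::distinct(grandparent_id)
    co <- gp_info |>
      dplyr::filter(is.na(death_year) | death_year > y,
                    y - birth_year >= 30,
                    grandparent_id %in% has_gc$grandparent_id)
    denom <- adults |>
      dplyr::filter(is.na(death_year) | death_year > y,
                    y - birth_year >= 30) |>
      dplyr::count(sex, name = "n30")
    gamma <- co |>
      dplyr::count(sex, name = "n_co") |>
      dplyr::right_join(denom, by = "sex") |>
      dplyr::mutate(
        n_co = dplyr::coalesce(.data$n_co, 0L),
        gamma_coreside = .data$n_co / .data$n30,
        moe90_gamma_coreside = z90 * sqrt(
          gamma_coreside * (1 - gamma_coreside) / .data$n30
        )
      )
    n_co_all <- max(nrow(co), 1L)
    p_race <- co |>
      dplyr::count(race_ethnicity, name = "n_r") |>
      dplyr::mutate(p_coreside_race = .data$n_r / n_co_all)
    p_mr <- mean(co$role %in% c("skip_gen", "most_responsible"))
    n_mr <- sum(co$role %in% c("skip_gen", "most_responsible"))
    q_sg <- if (n_mr > 0) sum(co$role == "skip_gen") / n_mr else 0
    tidyr::expand_grid(
      dplyr::select(gamma, sex, gamma_coreside, moe90_gamma_coreside),
      dplyr::select(p_race, race_ethnicity, p_coreside_race)
    ) |>
      dplyr::mutate(
        year = y, p_most_responsible = p_mr, q_skip_gen = q_sg,
        moe90_p_coreside_race = z90 * sqrt(
          p_coreside_race * (1 - p_coreside_race) / n_co_all
        ),
        moe90_p_most_responsible = z90 * sqrt(
          p_mr * (1 - p_mr) / n_co_all
        ),
        moe90_q_skip_gen = z90 * sqrt(
          q_sg * (1 - q_sg) / max(n_mr, 1)
        )
      ) |>
      dplyr::relocate(year, sex, race_ethnicity)
  })
}
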