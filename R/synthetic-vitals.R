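#' Configuration for the family-level microsimulation
#'
#' The generator emulates the statistical structure of national vital
#' registration: couples with age/sex/race/cause-stratified adult
#' mortality, age-stratified fertility, single-age child mortality, and
#' grandparents with co-residence caregiver roles. Defaults are of
#' realistic national magnitude: annual adult hazards rising from about
#' 1 per 1,000 at ages 15-19 to 0.15 at 85+, female fertility peaking
#' near 0.11 births per person-year at ages 25-29, and infant mortality
#' near 6 per 1,000. Two population groups with modestly different
#' mortality and fertility stand in for race/ethnicity strata.
#'
#' @param years Simulated calendar years (annual time steps).
#' @param n_families Number of couples.
#' @param races Tibble `race_ethnicity`, `prop`, `mortality_multiplier`,
#'   `fertility_multiplier`.
#' @param fertility Tibble `age_band`, `rate`: annual birth probability of
#'   a woman by maternal band.
#' @param father_age_dist Tibble `age_band`, `weight`: male fertility
#'   schedule from which the father's age is sampled, independent of the
#'   mother's.
#' @param mortality Tibble `age_band`, `hazard`: female baseline annual
#'   death hazard by adult band.
#' @param male_mortality_multiplier Multiplier on male hazards.
#' @param causes Tibble `cause`, `prob`: cause-of-death mix (sums to 1).
#' @param child_mortality Tibble `age` (0-17), `hazard`.
#' @param grandparent_roles Named probabilities (per grandparent) of the
#'   caregiver roles `skip_gen`, `most_responsible`, `housing_only`
#'   (their sum must be <= 1; the remainder is no caregiving role).
#' @param grandparent_gap Integer range of the grandmother/grandfather age
#'   gap to the mother.
#' @param fertility_coupling List `scenario` (`"none"`, `"zero_at_death"`,
#'   `"half_at_death"`), `onset`, `scale`: couples fertility to imminent
#'   parental death, reproducing the dampened-fertility scenarios.
#' @param seed Integer seed; runs are byte-identical given the seed.
#' @return A `kinloss_sim_config` list.
#' @export
sim_config <- function(years = 1985:2019,
                       n_families = 20000,
                       races = NULL,
                       fertility = NULL,
                       father_age_dist = NULL,
                       mortality = NULL,
                       male_mortality_multiplier = 1.4,
                       causes = NULL,
                       child_mortality = NULL,
                       grandparent_roles = c(skip_gen = 0.010,
                                             most_responsible = 0.020,
                                             housing_only = 0.030),
                       grandparent_gap = 22:35,
                       fertility_coupling = list(scenario = "none",
                                                 onset = 0, scale = 0.5),
                       seed = 1L) {
  if (is.null(races)) {
    races <- tibble::tibble(
      race_ethnicity = c("groupA", "groupB"),
      prop = c(0.7, 0.3),
      mortality_multiplier = c(1, 1.3),
      fertility_multiplier = c(1, 1.1)
    )
  }
  if (is.null(fertility)) {
    fertility <- tibble::tibble(
      age_band = mother_bands(),
      rate = c(0.030, 0.090, 0.110, 0.100, 0.050, 0.012, 0.002)
    )
  }
  if (is.null(father_age_dist)) {
    father_age_dist <- tibble::tibble(
      age_band = father_bands(),
      weight = c(0.02, 0.08, 0.12, 0.11, 0.06, 0.02, 0.008, 0.002, 0.001)
    )
  }
  if (is.null(mortality)) {
    mortality <- tibble::tibble(
      age_band = adult_bands(),
      hazard = c(0.0008, 0.0010, 0.0012, 0.0015, 0.0020, 0.0030, 0.0045,
                 0.0065, 0.0095, 0.0140, 0.0210, 0.0320, 0.0500, 0.0800,
                 0.1500)
    )
  }
  if (is.null(causes)) {
    causes <- tibble::tibble(
      cause = c("heart_disease", "malignant_neoplasms", "drug_overdose",
                "unintentional_injuries", "other"),
      prob = c(0.28, 0.24, 0.08, 0.10, 0.30)
    )
  }
  if (is.null(child_mortality)) {
    child_mortality <- tibble::tibble(
      age = 0:17,
      hazard = c(0.006, rep(0.0004, 4), rep(0.00015, 10), rep(0.0005, 3))
    )
  }
  cfg <- list(
    years = years, n_families = as.integer(n_families), races = races,
    fertility = fertility, father_age_dist = father_age_dist,
    mortality = mortality,
    male_mortality_multiplier = male_mortality_multiplier,
    causes = causes, child_mortality = child_mortality,
    grandparent_roles = grandparent_roles,
    grandparent_gap = grandparent_gap,
    fertility_coupling = fertility_coupling, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "kinloss_sim_config")
}

validate_sim_config <- function(cfg) {
  hz <- c(cfg$mortality$hazard,
          cfg$mortality$hazard * cfg$male_mortality_multiplier *
            max(cfg$races$mortality_multiplier),
          cfg$child_mortality$hazard, cfg$fertility$rate)
  if (any(hz < 0 | hz > 1)) {
    stop("configuration error: hazard or rate outside [0, 1]",
         call. = FALSE)
  }
  if (sum(cfg$grandparent_roles) > 1 + 1e-12) {
    stop("configuration error: grandparent role probabilities sum > 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$causes$prob) - 1) > 1e-8) {
    stop("configuration error: cause probabilities must sum to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

# annual hazard per adult given age, sex, race
.adult_hazard_fun <- function(cfg) {
  bands <- cfg$mortality$age_band
  base <- setNames(cfg$mortality$hazard, bands)
  rmult <- setNames(cfg$races$mortality_multiplier,
                    cfg$races$race_ethnicity)
  mmult <- cfg$male_mortality_multiplier
  function(age, sex, race) {
    b <- band_for_age(age, bands)
    h <- unname(base[b])
    h[is.na(h)] <- 0 # below 15: adults not yet at risk
    h * ifelse(sex == "male", mmult, 1) * unname(rmult[race])
  }
}

#' Simulate a cohort of families
#'
#' Annual discrete-time microsimulation. Each family holds a mother, a
#' father (age sampled from the male fertility schedule, independent of
#' the mother) and the mother's two parents as potential grandparent
#' caregivers. Within a year, births happen before deaths. Births require
#' both parents alive at the start of the year and within reproductive
#' ages (mothers 15-49, fathers 15-77); the birth probability is the
#' maternal-band fertility rate (optionally dampened near either parent's
#' death year in the coupling mode). Deaths are drawn from the stratified
#' hazards, with causes from the configured mix; children face single-age
#' hazards up to age 17.
#'
#' @param config A [sim_config()] object.
#' @return A `kinloss_linelist`: list with tibbles `individuals` (`id`,
#'   `role`, `family`, `sex`, `race_ethnicity`, `birth_year`,
#'   `death_year`, `cause`), `links` (`child_id`, `mother_id`,
#'   `father_id`) and `grandparent_roles` (`grandparent_id`, `child_id`,
#'   `role`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "kinloss_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  years <- config$years
  y0 <- min(years); y1 <- max(years)
  n <- config$n_families

  race <- sample(config$races$race_ethnicity, n, replace = TRUE,
                 prob = config$races$prop)
  mother_birth <- sample(seq(y0 - 49, y1 - 15), n, replace = TRUE)
  # father age relative to a fixed maternal reference age of 27, drawn
  # from the male fertility schedule
  fb <- band_bounds(config$father_age_dist$age_band)
  f_band <- sample(seq_len(nrow(fb)), n, replace = TRUE,
                   prob = config$father_age_dist$weight)
  f_age_ref <- fb$lo[f_band] +
    floor(runif(n) * (pmin(fb$hi[f_band], 77) - fb$lo[f_band] + 1))
  father_birth <- mother_birth + 27 - f_age_ref
  gm_birth <- mother_birth - sample(config$grandparent_gap, n, TRUE)
  gf_birth <- mother_birth - sample(config$grandparent_gap, n, TRUE)

  adults <- tibble::tibble(
    id = seq_len(4L * n),
    role = rep(c("mother", "father", "grandmother", "grandfather"),
               each = n),
    family = rep(seq_len(n), 4L),
    sex = rep(c("female", "male", "female", "male"), each = n),
    race_ethnicity = rep(race, 4L),
    birth_year = c(mother_birth, father_birth, gm_birth, gf_birth)
  )

  # adult mortality over the simulated years
  hfun <- .adult_hazard_fun(config)
  death_year <- rep(NA_integer_, nrow(adults))
  alive <- rep(TRUE, nrow(adults))
  for (y in years) {
    age <- y - adults$birth_year
    at_risk <- alive & age >= 15
    if (!any(at_risk)) next
    h <- hfun(age[at_risk], adults$sex[at_risk],
              adults$race_ethnicity[at_risk])
    dies <- runif(sum(at_risk)) < h
    idx <- which(at_risk)[dies]
    death_year[idx] <- y
    alive[idx] <- FALSE
  }
  adults$death_year <- death_year
  n_dead <- sum(!is.na(death_year))
  adults$cause <- NA_character_
  if (n_dead > 0) {
    adults$cause[!is.na(death_year)] <- sample(
      config$causes$cause, n_dead, replace = TRUE,
      prob = config$causes$prob
    )
  }

  # births: maternal-band rates, both parents alive at start of year,
  # optional dampening near either parent's death
  frate <- setNames(config$fertility$rate, config$fertility$age_band)
  fmult <- setNames(config$races$fertility_multiplier,
                    config$races$race_ethnicity)
  m_death <- adults$death_year[adults$role == "mother"]
  f_death <- adults$death_year[adults$role == "father"]
  cpl <- config$fertility_coupling
  damp <- function(dy, y) {
    if (identical(cpl$scenario, "none") || all(is.na(dy))) {
      return(rep(1, length(dy)))
    }
    out <- rep(1, length(dy))
    has <- !is.na(dy) & dy >= y
    out[has] <- dampen_fertility(1, dy[has] - y, cpl$scenario,
                                 onset = cpl$onset,
                                 scale = cpl$scale %||% 0.5)
    out
  }
  kids <- vector("list", length(years))
  for (y in years) {
    m_age <- y - mother_birth
    f_age <- y - father_birth
    ok <- (is.na(m_death) | m_death >= y) & (is.na(f_death) | f_death >= y) &
      m_age >= 15 & m_age <= 49 & f_age >= 15 & f_age <= 77
    if (!any(ok)) next
    mb <- band_for_age(m_age[ok], names(frate))
    p <- unname(frate[mb]) * unname(fmult[race[ok]]) *
      damp(m_death[ok], y) * damp(f_death[ok], y)
    born <- runif(sum(ok)) < p
    fam <- which(ok)[born]
    if (!length(fam)) next
    kids[[y - y0 + 1L]] <- tibble::tibble(
      family = fam, birth_year = y,
      sex = sample(c("female", "male"), length(fam), replace = TRUE),
      race_ethnicity = race[fam]
    )
  }
  children <- dplyr::bind_rows(kids)
  if (nrow(children)) {
    children$id <- 4L * n + seq_len(nrow(children))
    # child mortality by single age through 17
    ch <- setNames(config$child_mortality$hazard,
                   config$child_mortality$age)
    cdeath <- rep(NA_integer_, nrow(children))
    calive <- rep(TRUE, nrow(children))
    for (y in years) {
      cage <- y - children$birth_year
      at_risk <- calive & cage >= 0 & cage <= 17
      if (!any(at_risk)) next
      p <- unname(ch[as.character(cage[at_risk])])
      dies <- runif(sum(at_risk)) < p
      idx <- which(at_risk)[dies]
      cdeath[idx] <- y
      calive[idx] <- FALSE
    }
    children$death_year <- cdeath
    children$cause <- NA_character_
    children$role <- "child"
    links <- tibble::tibble(
      child_id = children$id,
      mother_id = children$family,
      father_id = n + children$family
    )
  } else {
    children <- tibble::tibble(
      family = integer(), birth_year = integer(), sex = character(),
      race_ethnicity = character(), id = integer(),
      death_year = integer(), cause = character(), role = character()
    )
    links <- tibble::tibble(child_id = integer(), mother_id = integer(),
                            father_id = integer())
  }

  # grandparent caregiver roles (per grandparent, covering the family's
  # children)
  gp <- dplyr::filter(adults, role %in% c("grandmother", "grandfather"))
  pr <- config$grandparent_roles
  role_draw <- sample(
    c(names(pr), "none"), nrow(gp), replace = TRUE,
    prob = c(unname(pr), 1 - sum(pr))
  )
  gp_roles <- tibble::tibble(
    grandparent_id = gp$id, family = gp$family, role = role_draw
  ) |>
    dplyr::filter(role != "none") |>
    dplyr::inner_join(
      dplyr::select(children, child_id = id, family),
      by = "family", relationship = "many-to-many"
    ) |>
    dplyr::select(grandparent_id, child_id, role)

  individuals <- dplyr::bind_rows(
    adults,
    dplyr::select(children, id, role, family, sex, race_ethnicity,
                  birth_year, death_year, cause)
  )
  structure(
    list(individuals = individuals, links = links,
         grandparent_roles = gp_roles, years = years,
         config = config),
    class = "kinloss_linelist"
  )
}

#' @export
print.kinloss_linelist <- function(x, ...) {
  n_child <- sum(x$individuals$role == "child")
  cat("<kinloss_linelist> ", format(x$config$n_families, big.mark = ","),
      " families, ", format(n_child, big.mark = ","), " children, years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
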