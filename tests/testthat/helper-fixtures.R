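# Shared fixture builders. All fixtures are generated in code.

tiny_mortality <- function() {
  tibble::tibble(
    year = c(2000, 2000, 2001),
    age_band = c("30-34", "35-39", "30-34"),
    sex = c("female", "male", "female"),
    race_ethnicity = "groupA",
    cause = c("heart_disease", "drug_overdose", "heart_disease"),
    count = c(10, 20, 12)
  )
}

write_tmp_csv <- function(x, name = "table.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  readr::write_csv(x, path)
  path
}

# small cause map with the drug-overdose recategorization
toy_cause_map <- function() {
  tibble::tibble(
    source_code = c("X40", "X41", "X42", "X43", "X44",
                    "X60", "X61", "X62", "X63", "X64",
                    "X85", "Y10", "Y11", "Y12", "Y13", "Y14",
                    "U071", "I21", "C50", "X95"),
    scheme = "ICD10_113recode",
    target = c(rep("drug_overdose", 16),
               "covid19", "heart_disease", "malignant_neoplasms",
               "homicide_excl_overdose")
  )
}

# hand-built line list: one family, configurable death years
manual_linelist <- function(m_death = NA, f_death = NA, child_birth = 2000,
                            child_death = NA, years = 1995:2020,
                            gp_role = NULL, gm_death = NA) {
  individuals <- tibble::tibble(
    id = 1:5,
    role = c("mother", "father", "grandmother", "grandfather", "child"),
    family = 1L,
    sex = c("female", "male", "female", "male", "female"),
    race_ethnicity = "groupA",
    birth_year = c(1970L, 1968L, 1945L, 1944L, as.integer(child_birth)),
    death_year = as.integer(c(m_death, f_death, gm_death, NA, child_death)),
    cause = c(ifelse(is.na(m_death), NA, "heart_disease"),
              ifelse(is.na(f_death), NA, "drug_overdose"),
              ifelse(is.na(gm_death), NA, "heart_disease"), NA, NA)
  )
  links <- tibble::tibble(child_id = 5L, mother_id = 1L, father_id = 2L)
  gpr <- if (is.null(gp_role)) {
    tibble::tibble(grandparent_id = integer(), child_id = integer(),
                   role = character())
  } else {
    tibble::tibble(grandparent_id = 3L, child_id = 5L, role = gp_role)
  }
  structure(
    list(individuals = individuals, links = links,
         grandparent_roles = gpr, years = years,
         config = sim_config(years = years, n_families = 1)),
    class = "kinloss_linelist"
  )
}

# constant-rate inputs for closed-form orphanhood checks
flat_inputs <- function(years = 1990:2010, rate = 0.1, hazard = 0.002,
                        child_hazard = 0) {
  bands <- adult_bands()
  pop <- tidyr::expand_grid(
    year = years, age_band = bands,
    sex = c("female", "male"), race_ethnicity = "groupA"
  ) |> dplyr::mutate(count = 1000)
  deaths <- pop |>
    dplyr::mutate(count = 1000 * hazard * 5, cause = "all")
  fert <- tidyr::expand_grid(
    year = years,
    age_band = c(mother_bands(), father_bands()),
    sex = c("female", "male"), race_ethnicity = "groupA"
  ) |>
    dplyr::filter((sex == "female" & age_band %in% mother_bands()) |
                    (sex == "male" & age_band %in% father_bands())) |>
    dplyr::mutate(rate = rate)
  surv <- tidyr::expand_grid(birth_year = (min(years) - 17):max(years),
                             age = 0:17) |>
    dplyr::mutate(p_survive = 1)
  chz <- tidyr::expand_grid(year = years, age = 0:17,
                            race_ethnicity = "groupA") |>
    dplyr::mutate(hazard = child_hazard)
  list(population = pop, deaths = deaths, fertility = fert,
       child_survival = surv, child_hazards = chz)
}
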