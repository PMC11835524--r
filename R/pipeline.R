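#' Run the full kin-loss estimation pipeline
#'
#' Configuration-driven end-to-end runner: validates the input tables,
#' harmonizes causes and applies comparability ratios where configured,
#' computes fertility rates, expected children, mortality hazards,
#' de-duplicated orphanhood incidence, survival-adjusted prevalence and —
#' when co-residence proportions are supplied — grandparent caregiver
#' loss, de-duplication and combined caregiver-loss prevalence. With
#' `n_rep > 1` the whole computation is repeated over co-monotone Poisson
#' replicates of the count tables (and normal replicates of the
#' comparability ratios and co-residence proportions) and the headline
#' series are summarized with 95% uncertainty intervals.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   * `tables`: named list of tibbles or file paths — `mortality`,
#'     `natality`, `population`, `child_mortality`, `child_population`,
#'     `child_survival` required; `caregiver_proportions`, `cause_map`,
#'     `comparability` optional.
#'   * `years`: incidence years to estimate.
#'   * `prevalence_years`: years for prevalence (each needs a 17-year
#'     incidence history within `years`); default: the latest feasible
#'     years.
#'   * `fertility_reference_year`: optional backfill reference for
#'     [extend_historic()].
#'   * `icd9_years`: years to which comparability ratios apply.
#'   * `seed`, `n_rep` (default 1), `mode` (`"national"`), `dedup`
#'     (arguments to [dedup_params()]).
#' @param out_dir Optional directory; when given, incidence, prevalence,
#'   caregiver-loss and summary CSVs plus a YAML run log of all settings
#'   are written there.
#' @return A `kinloss_result` list (tibbles `fertility`, `hazards`,
#'   `child_hazards`, `incidence`, `incidence_by_sex`, `prevalence`,
#'   `prevalence_by_sex`, optional `grandparent`, `caregiver_incidence`,
#'   `caregiver_prevalence`, `summary`, plus `settings`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  tabs <- .load_config_tables(config)
  years <- .parse_years(config$years %||%
                          stop("missing input: years", call. = FALSE))
  .check_year_coverage(tabs, years)
  prevalence_years <- .parse_years(
    config$prevalence_years %||% years[years - 17 >= min(years)]
  )
  if (!length(prevalence_years)) prevalence_years <- max(years)
  n_rep <- config$n_rep %||% 1L
  seed <- config$seed %||% 1L
  opts <- list(
    years = years, prevalence_years = prevalence_years,
    fertility_reference_year = config$fertility_reference_year,
    icd9_years = config$icd9_years,
    dedup = do.call(dedup_params, config$dedup %||% list())
  )
  set.seed(seed)
  res <- .estimate_once(tabs, opts)
  res$settings <- list(
    years = years, prevalence_years = prevalence_years, seed = seed,
    n_rep = n_rep, mode = config$mode %||% "national",
    dedup = unclass(opts$dedup),
    fertility_reference_year = opts$fertility_reference_year,
    icd9_years = opts$icd9_years,
    quantile_rule = "type 7 (linear interpolation between order statistics)"
  )
  if (n_rep > 1) {
    res$replicates <- .replicate_totals(tabs, opts, n_rep, seed)
    res$summary_ui <- summarize_replicates(
      res$replicates, value = "count", by = c("year", "measure")
    )
  }
  class(res) <- "kinloss_result"
  if (!is.null(out_dir)) .write_result(res, out_dir)
  res
}

# years may arrive as an integer vector, a list, or a "2002:2019" range
# string (the YAML-friendly form)
.parse_years <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl("^\\d{4}:\\d{4}$", x)) {
    parts <- as.integer(strsplit(x, ":")[[1]])
    return(seq(parts[1], parts[2]))
  }
  out <- suppressWarnings(as.integer(unlist(x)))
  if (anyNA(out)) {
    stop("configuration error: unparseable years specification",
         call. = FALSE)
  }
  out
}

.load_config_tables <- function(config) {
  tables <- config$tables %||% stop("missing input: tables", call. = FALSE)
  required <- c("mortality", "natality", "population", "child_mortality",
                "child_population", "child_survival")
  missing <- setdiff(required, names(tables))
  if (length(missing)) {
    stop("missing input table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::imap(tables, function(x, kind) {
    k <- if (kind %in% c("mortality", "natality", "population",
                         "child_mortality", "child_population",
                         "child_survival", "cause_map", "comparability",
                         "caregiver_proportions")) kind else "mortality"
    if (is.character(x)) load_vital_table(x, k) else validate_vital_table(x, k)
  })
}

.check_year_coverage <- function(tabs, years) {
  for (nm in c("mortality", "population")) {
    gaps <- setdiff(years, unique(tabs[[nm]]$year))
    if (length(gaps)) {
      stop("inconsistent year coverage: ", nm, " table missing year(s) ",
           paste(sort(gaps), collapse = ", "), call. = FALSE)
    }
  }
}

# One full point estimate over prepared tables.
.estimate_once <- function(tabs, opts) {
  years <- opts$years
  deaths <- tabs$mortality
  if ("cause_code" %in% names(deaths) && !is.null(tabs$cause_map)) {
    deaths <- map_causes(deaths, tabs$cause_map)
  }
  if (!"cause" %in% names(deaths)) deaths$cause <- "all"
  if (!is.null(tabs$comparability) && length(opts$icd9_years)) {
    deaths <- apply_comparability(deaths, tabs$comparability,
                                  opts$icd9_years)
  }
  fr <- compute_fertility(tabs$natality, tabs$population)
  if (!is.null(opts$fertility_reference_year)) {
    fr <- extend_historic(fr, opts$fertility_reference_year,
                          min(years) - 17)
  }
  child_h <- mortality_hazard(tabs$child_mortality, tabs$child_population,
                              n = 1)
  ec <- expected_children(fr, tabs$child_survival, years)
  hz <- mortality_hazard(deaths, tabs$population, n = 5) |>
    dplyr::filter(age_band %in% adult_bands())
  hz_full <- complete_hazards(hz)
  comp <- incidence_components(ec, dplyr::filter(deaths, year %in% years),
                               hz_full)
  new_band <- combine_incidence(comp)
  new_by_sex_band <- incidence_by_sex(comp, keep_band = TRUE)
  incidence <- new_band |>
    dplyr::group_by(year, race_ethnicity, child_age, cause) |>
    dplyr::summarise(new = sum(new), .groups = "drop")
  incidence_sex <- new_by_sex_band |>
    dplyr::group_by(year, sex, race_ethnicity, child_age, cause) |>
    dplyr::summarise(new = sum(new), .groups = "drop")
  prevalence <- accumulate_prevalence(incidence, child_h,
                                      opts$prevalence_years)
  prevalence_sex <- accumulate_prevalence(incidence_sex, child_h,
                                          opts$prevalence_years)
  out <- list(
    fertility = fr, hazards = hz, child_hazards = child_h,
    components = comp, incidence = incidence,
    incidence_by_sex = incidence_sex, prevalence = prevalence,
    prevalence_by_sex = prevalence_sex
  )
  if (!is.null(tabs$caregiver_proportions)) {
    props <- caregiver_proportions(tabs$caregiver_proportions,
                                   years = years)
    g <- grandparent_incidence(props, dplyr::filter(deaths,
                                                    year %in% years))
    g_age <- disaggregate_child_age(g, new_by_sex_band,
                                    mode = "cause_specific")
    parent_h <- .parent_hazards(deaths, tabs$population, tabs$natality,
                                years)
    g_dedup_age <- dedup_caregiver(g_age, opts$dedup, parent_h,
                                   orphan_new = incidence_sex)
    l_new <- g_dedup_age |>
      dplyr::group_by(year, sex, race_ethnicity, cause) |>
      dplyr::summarise(g_dedup = sum(g_dedup), l_new = sum(.data$l_new),
                       .groups = "drop")
    cg_prev <- caregiver_prevalence(
      prevalence_sex,
      dplyr::select(g_dedup_age, year, sex, race_ethnicity, cause,
                    child_age, g_dedup),
      child_h, opts$prevalence_years
    )
    out$grandparent <- g
    out$grandparent_by_age <- g_age
    out$caregiver_incidence <- l_new
    out$caregiver_prevalence <- cg_prev
  }
  out$summary <- .headline_series(out)
  out
}

# parent-age-weighted all-cause mortality rates, weighted by the birth
# composition of parental ages (the parent age composition); weights are
# renormalized over the bands with population exposure
.parent_hazards <- function(deaths, population, natality, years) {
  keys <- c("year", "age_band", "sex", "race_ethnicity")
  rates <- population |>
    dplyr::filter(year %in% years, count > 0) |>
    dplyr::select(dplyr::all_of(keys), count_p = count) |>
    dplyr::left_join(
      deaths |>
        dplyr::filter(year %in% years) |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(count_d = sum(count), .groups = "drop"),
      by = keys
    ) |>
    dplyr::mutate(rate = dplyr::coalesce(count_d, 0) / count_p) |>
    dplyr::select(dplyr::all_of(keys), rate) |>
    dplyr::filter(age_band %in% adult_bands())
  weights <- natality |>
    dplyr::filter(year %in% years) |>
    dplyr::group_by(year, sex, race_ethnicity) |>
    dplyr::mutate(weight = count / sum(count)) |>
    dplyr::ungroup() |>
    dplyr::select(year, age_band, sex, race_ethnicity, weight)
  # paternal 55-77 births weight the overlapping five-year bands equally
  wb <- weights |>
    dplyr::mutate(age_band = as.character(age_band))
  split77 <- wb |> dplyr::filter(age_band == "55-77")
  if (nrow(split77)) {
    bands5 <- c("55-59", "60-64", "65-69", "70-74", "75-79")
    wb <- dplyr::bind_rows(
      dplyr::filter(wb, age_band != "55-77"),
      tidyr::expand_grid(dplyr::select(split77, -age_band),
                         age_band = bands5) |>
        dplyr::mutate(weight = weight / length(bands5))
    ) |>
      dplyr::group_by(year, age_band, sex, race_ethnicity) |>
      dplyr::summarise(weight = sum(weight), .groups = "drop")
  }
  wb <- wb |>
    dplyr::semi_join(rates, by = keys) |>
    dplyr::group_by(year, sex, race_ethnicity) |>
    dplyr::mutate(weight = weight / sum(weight)) |>
    dplyr::ungroup()
  parent_hazard_aggregate(rates, wb)
}

# headline incidence/prevalence series by measure
.headline_series <- function(out) {
  res <- dplyr::bind_rows(
    out$incidence |>
      dplyr::group_by(year) |>
      dplyr::summarise(count = sum(new), .groups = "drop") |>
      dplyr::mutate(measure = "orphanhood_incidence"),
    out$prevalence |>
      dplyr::group_by(year) |>
      dplyr::summarise(count = sum(lifetime), .groups = "drop") |>
      dplyr::mutate(measure = "orphanhood_prevalence")
  )
  if (!is.null(out$grandparent)) {
    res <- dplyr::bind_rows(
      res,
      out$grandparent |>
        dplyr::group_by(year, category) |>
        dplyr::summarise(count = sum(g_loss), .groups = "drop") |>
        dplyr::mutate(measure = paste0("grandparent_", category,
                                       "_incidence")) |>
        dplyr::select(-category),
      out$caregiver_incidence |>
        dplyr::group_by(year) |>
        dplyr::summarise(count = sum(.data$l_new), .groups = "drop") |>
        dplyr::mutate(measure = "caregiver_incidence"),
      out$caregiver_prevalence |>
        dplyr::group_by(year) |>
        dplyr::summarise(count = sum(.data$l_lifetime), .groups = "drop") |>
        dplyr::mutate(measure = "caregiver_prevalence")
    )
  }
  dplyr::relocate(res, year, measure, count)
}

# per-replicate headline series under co-monotone Poisson noise on the
# count tables and normal noise on ratios/proportions
.replicate_totals <- function(tabs, opts, n_rep, seed) {
  set.seed(seed)
  noisy <- list(
    mortality = poisson_comonotone(tabs$mortality, n_rep),
    natality = poisson_comonotone(tabs$natality, n_rep),
    population = poisson_comonotone(tabs$population, n_rep),
    child_mortality = poisson_comonotone(tabs$child_mortality, n_rep),
    child_population = poisson_comonotone(tabs$child_population, n_rep)
  )
  if (!is.null(tabs$comparability)) {
    if (!"sd" %in% names(tabs$comparability)) tabs$comparability$sd <- 0
    noisy$comparability <- resample_ratios(tabs$comparability, n_rep)
  }
  if (!is.null(tabs$caregiver_proportions)) {
    cp <- tabs$caregiver_proportions
    for (col in c("gamma_coreside", "p_coreside_race",
                  "p_most_responsible", "q_skip_gen")) {
      moe <- paste0("moe90_", col)
      sdv <- if (moe %in% names(cp)) cp[[moe]] / moe90_to_sd_factor() else 0
      cp[[paste0("sd_", col)]] <- sdv
    }
    noisy$caregiver_proportions <- cp
  }
  purrr::map_dfr(seq_len(n_rep), function(k) {
    tk <- tabs
    for (nm in c("mortality", "natality", "population", "child_mortality",
                 "child_population")) {
      tk[[nm]] <- noisy[[nm]] |>
        dplyr::filter(replicate == k) |>
        dplyr::select(-replicate)
      # guard zero-population cells in the replicate
      if (nm %in% c("population", "child_population")) {
        tk[[nm]]$count <- pmax(tk[[nm]]$count, 1)
      }
    }
    if (!is.null(noisy$comparability)) {
      tk$comparability <- noisy$comparability |>
        dplyr::filter(replicate == k) |>
        dplyr::select(-replicate)
    }
    if (!is.null(noisy$caregiver_proportions)) {
      cp <- noisy$caregiver_proportions
      for (col in c("gamma_coreside", "p_coreside_race",
                    "p_most_responsible", "q_skip_gen")) {
        cp[[col]] <- pmin(1, pmax(0, rnorm(nrow(cp), cp[[col]],
                                           cp[[paste0("sd_", col)]])))
      }
      tk$caregiver_proportions <- cp |>
        dplyr::select(-dplyr::starts_with("sd_"))
    }
    .estimate_once(tk, opts)$summary |>
      dplyr::mutate(replicate = k)
  })
}

.write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, nm) {
    if (!is.null(x)) {
      readr::write_csv(x, file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  wr(res$incidence, "incidence")
  wr(res$incidence_by_sex, "incidence_by_sex")
  wr(res$prevalence, "prevalence")
  wr(res$caregiver_incidence, "caregiver_incidence")
  wr(res$caregiver_prevalence, "caregiver_prevalence")
  wr(res$summary, "summary")
  wr(res$summary_ui, "summary_ui")
  yaml::write_yaml(res$settings, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
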