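#' Derive grandparent caregiver co-residence proportions
#'
#' From survey-style inputs — the sex-specific share of adults aged 30+
#' living with grandchildren (`gamma_coreside`), the race share of
#' co-residers (`p_coreside_race`), the share providing most basic needs
#' (`p_most_responsible`) and, of those, the share with no parent present
#' (`q_skip_gen`) — derives the three caregiver-type proportions:
#' * `gamma_skip_gen = gamma * p_r * p_mr * q_sg`
#' * `gamma_mr_not_sg = gamma * p_r * p_mr * (1 - q_sg)`
#' * `gamma_co_not_mr = gamma * p_r * (1 - p_mr)`
#'
#' The three sum exactly to `gamma * p_r`. Sex-by-race independence of the
#' factorization is the stated working assumption; a full joint table can
#' be supplied by pre-computing the `gamma_*` columns directly. Years
#' before the earliest surveyed year reuse that year's values (the study
#' backfills pre-2010 years with 2010).
#'
#' @param acs Tibble with columns `year`, `sex`, `race_ethnicity`,
#'   `gamma_coreside`, `p_coreside_race`, `p_most_responsible`,
#'   `q_skip_gen` (optional `state`, `moe90_*`).
#' @param years Optional years to expand to; years before the earliest
#'   surveyed year get that year's values.
#' @return Input tibble with the three derived `gamma_*` columns, expanded
#'   to `years` when given.
#' @export
caregiver_proportions <- function(acs, years = NULL) {
  pcols <- c("gamma_coreside", "p_coreside_race", "p_most_responsible",
             "q_skip_gen")
  for (col in pcols) {
    if (any(acs[[col]] < 0 | acs[[col]] > 1, na.rm = TRUE)) {
      stop("configuration error: ", col, " outside [0, 1]", call. = FALSE)
    }
  }
  out <- acs |>
    dplyr::mutate(
      gamma_skip_gen = gamma_coreside * p_coreside_race *
        p_most_responsible * q_skip_gen,
      gamma_mr_not_sg = gamma_coreside * p_coreside_race *
        p_most_responsible * (1 - q_skip_gen),
      gamma_co_not_mr = gamma_coreside * p_coreside_race *
        (1 - p_most_responsible)
    )
  if (!is.null(years)) {
    y0 <- min(out$year)
    first <- dplyr::filter(out, year == y0)
    back <- purrr::map_dfr(setdiff(years[years < y0], out$year),
                           function(y) dplyr::mutate(first, year = y))
    out <- dplyr::bind_rows(back, dplyr::filter(out, year %in% years)) |>
      dplyr::arrange(year)
  }
  out
}

#' Grandparent caregiver-loss incidence from deaths of adults 30+
#'
#' Each deceased grandparent caregiver is attributed a minimum of one
#' grandchild: `G^x = 1 * gamma^x * sum(D over age bands 30+)` for each of
#' the three caregiver types. Primary caregiver loss is the skip-generation
#' plus most-responsible types; secondary is the co-residing
#' housing-provider type.
#'
#' @param props Output of [caregiver_proportions()].
#' @param deaths Cause-mapped mortality tibble containing age bands at 30+.
#' @param min_age Minimum caregiver age (30).
#' @return Long tibble `year`, (`state`,) `sex`, `race_ethnicity`, `cause`,
#'   `caregiver_type` (`skip_gen`, `most_responsible_not_sg`,
#'   `co_reside_not_mr`), `category` (`primary`/`secondary`), `g_loss`.
#' @export
grandparent_incidence <- function(props, deaths, min_age = 30) {
  keep <- band_bounds(deaths$age_band)$lo >= min_age
  if (!any(keep)) {
    stop("estimation error: mortality table has no age bands at ",
         min_age, "+", call. = FALSE)
  }
  keys <- intersect(c("year", "state", "sex", "race_ethnicity", "cause"),
                    names(deaths))
  d30 <- deaths[keep, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(deaths_30plus = sum(count), .groups = "drop")
  jn <- intersect(c("year", "state", "sex", "race_ethnicity"), names(props))
  d30 |>
    dplyr::inner_join(
      dplyr::select(props, dplyr::all_of(jn), gamma_skip_gen,
                    gamma_mr_not_sg, gamma_co_not_mr),
      by = jn
    ) |>
    tidyr::pivot_longer(
      dplyr::starts_with("gamma_"),
      names_to = "caregiver_type", names_prefix = "gamma_",
      values_to = "gamma"
    ) |>
    dplyr::mutate(
      caregiver_type = dplyr::recode(caregiver_type,
        skip_gen = "skip_gen",
        mr_not_sg = "most_responsible_not_sg",
        co_not_mr = "co_reside_not_mr"
      ),
      category = ifelse(caregiver_type == "co_reside_not_mr",
                        "secondary", "primary"),
      g_loss = 1 * .data$gamma * .data$deaths_30plus
    ) |>
    dplyr::select(dplyr::all_of(keys), caregiver_type, category, g_loss)
}

#' Disaggregate grandparent caregiver loss by child age
#'
#' Splits caregiver-loss counts across child ages 0-17 using the age
#' composition of children who lost parents aged 30+, pooled over years:
#' cause-specific weights by default, all-cause pooled weights as a
#' sensitivity mode, or externally supplied survey weights. Strata whose
#' composition is entirely zero fall back to uniform weights with a
#' warning. The split conserves totals exactly.
#'
#' @param g Output of [grandparent_incidence()].
#' @param orphan_composition Orphanhood incidence by parental age band and
#'   sex ([incidence_by_sex()] with `keep_band = TRUE`), used as the
#'   composition numerator after restriction to bands 30+ and summation
#'   over years and bands.
#' @param mode `"cause_specific"`, `"all_cause"`, or `"external"`.
#' @param weights For `mode = "external"`: tibble `child_age`, `weight`
#'   (summing to 1).
#' @param min_age Minimum parental age for the composition (30).
#' @return `g` with an additional `child_age` column; `g_loss` split.
#' @export
disaggregate_child_age <- function(g, orphan_composition = NULL,
                                   mode = c("cause_specific", "all_cause",
                                            "external"),
                                   weights = NULL, min_age = 30) {
  mode <- match.arg(mode)
  ages <- 0:17
  if (identical(mode, "external")) {
    stopifnot(!is.null(weights),
              abs(sum(weights$weight) - 1) < 1e-8)
    return(
      tidyr::expand_grid(g, child_age = ages) |>
        dplyr::left_join(weights, by = "child_age") |>
        dplyr::mutate(g_loss = g_loss * weight) |>
        dplyr::select(-weight)
    )
  }
  stopifnot(!is.null(orphan_composition))
  keep <- band_bounds(orphan_composition$age_band)$lo >= min_age
  grp <- intersect(c("state", "sex", "race_ethnicity",
                     if (identical(mode, "cause_specific")) "cause"),
                   names(orphan_composition))
  comp <- orphan_composition[keep, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "child_age")))) |>
    dplyr::summarise(num = sum(new), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(grp)), child_age = ages,
      fill = list(num = 0)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      denom = sum(.data$num),
      weight = ifelse(denom > 0, .data$num / denom, 1 / length(ages))
    ) |>
    dplyr::ungroup()
  if (any(comp$denom == 0)) {
    warning("all-zero orphanhood composition in some strata; ",
            "uniform child-age weights used there")
  }
  out <- tidyr::expand_grid(g, child_age = ages) |>
    dplyr::left_join(
      dplyr::select(comp, dplyr::all_of(grp), child_age, weight),
      by = c(grp, "child_age")
    )
  if (anyNA(out$weight)) {
    warning("strata without orphanhood composition; uniform weights used")
    out$weight[is.na(out$weight)] <- 1 / length(ages)
  }
  out |>
    dplyr::mutate(g_loss = g_loss * weight) |>
    dplyr::select(-weight)
}

#' De-duplication parameters for combined caregiver loss
#'
#' Defaults: 11% of skip-generation grandchildren had already lost a
#' parent; 11% of single-parent co-residing grandchildren had lost the
#' other parent; 70% of non-skip-generation co-residing grandchildren
#' lived with both parents; and parents are exposed for 6/12 of a year on
#' average after the survey reference point.
#'
#' @param p_skip_gen_parent_died,p_other_parent_died,p_both_parents_present
#'   Probabilities in `[0, 1]`.
#' @param exposure_fraction Fraction of the year parents remain exposed
#'   after the survey (6/12).
#' @return Named list of class `dedup_params`.
#' @export
dedup_params <- function(p_skip_gen_parent_died = 0.11,
                         p_other_parent_died = 0.11,
                         p_both_parents_present = 0.70,
                         exposure_fraction = 6 / 12) {
  p <- c(p_skip_gen_parent_died, p_other_parent_died,
         p_both_parents_present, exposure_fraction)
  if (any(p < 0 | p > 1)) {
    stop("configuration error: de-duplication probability outside [0, 1]",
         call. = FALSE)
  }
  structure(
    list(
      p_skip_gen_parent_died = p_skip_gen_parent_died,
      p_other_parent_died = p_other_parent_died,
      p_both_parents_present = p_both_parents_present,
      exposure_fraction = exposure_fraction
    ),
    class = "dedup_params"
  )
}

#' Parent-age-weighted aggregate mortality rate
#'
#' Weighted mean of age-band-specific mortality rates using parental age
#' compositions as weights; yields the aggregate parental hazard
#' `h_parent(y, s, r)` used in the de-duplication adjustment.
#'
#' @param rates Tibble with `age_band`, `rate` and optional strata columns.
#' @param parent_age_weights Tibble with `age_band`, `weight` (and
#'   matching strata columns); weights must sum to 1 (within 1e-9) in each
#'   stratum.
#' @return Tibble of strata plus `hazard`.
#' @export
parent_hazard_aggregate <- function(rates, parent_age_weights) {
  jn <- intersect(setdiff(names(rates), "rate"),
                  setdiff(names(parent_age_weights), "weight"))
  grp <- setdiff(jn, "age_band")
  sums <- parent_age_weights |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(s = sum(weight), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    stop("configuration error: parent age weights do not sum to 1",
         call. = FALSE)
  }
  rates |>
    dplyr::inner_join(parent_age_weights, by = jn) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(hazard = sum(rate * weight), .groups = "drop")
}

#' De-duplicate grandparent caregiver loss against orphanhood
#'
#' Removes from the grandparent caregiver-loss counts the grandchildren
#' already counted under orphanhood: skip-generation losses are reduced by
#' the share whose parent had previously died and by the probability that
#' a parent dies in the residual exposure window; other co-residing losses
#' by the share living with a previously widowed single parent and the
#' same residual-window factor:
#'
#' `G_dedup = G_sg (1 - p_sg_died) (1 - (h_M + h_F - h_M h_F) e)
#'          + (G_mr + G_co) (p_both + (1 - p_both)(1 - p_other_died))
#'            (1 - (h_M + h_F - h_M h_F) e)`
#'
#' Combined caregiver-loss incidence is `L_new = O_new + G_dedup`.
#'
#' @param g Output of [grandparent_incidence()] or
#'   [disaggregate_child_age()].
#' @param params A [dedup_params()] object.
#' @param parent_hazards Tibble `year`, (`race_ethnicity`,) `sex`, `hazard`
#'   of parent-age-weighted mortality rates (both sexes present).
#' @param orphan_new Optional orphanhood incidence ([incidence_by_sex()])
#'   to add for `l_new`; joined on the shared stratum columns.
#' @return Tibble of strata plus `g_dedup` (and `l_new` when `orphan_new`
#'   is given).
#' @export
dedup_caregiver <- function(g, params = dedup_params(), parent_hazards,
                            orphan_new = NULL) {
  stopifnot(inherits(params, "dedup_params"))
  hw <- parent_hazards |>
    tidyr::pivot_wider(names_from = sex, values_from = hazard,
                       names_prefix = "h_")
  jn <- intersect(c("year", "state", "race_ethnicity"), names(hw))
  wide <- g |>
    dplyr::select(-dplyr::any_of("category")) |>
    tidyr::pivot_wider(names_from = caregiver_type, values_from = g_loss,
                       values_fill = 0)
  for (col in c("skip_gen", "most_responsible_not_sg", "co_reside_not_mr")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide <- dplyr::left_join(wide, hw, by = jn)
  if (anyNA(wide$h_female) || anyNA(wide$h_male)) {
    stop("estimation error: parent hazards missing for some strata",
         call. = FALSE)
  }
  e <- params$exposure_fraction
  wide <- wide |>
    dplyr::mutate(
      resid = 1 - (.data$h_male + .data$h_female -
                     .data$h_male * .data$h_female) * e,
      g_dedup = .data$skip_gen * (1 - params$p_skip_gen_parent_died) *
        .data$resid +
        (.data$most_responsible_not_sg + .data$co_reside_not_mr) *
          (params$p_both_parents_present +
             (1 - params$p_both_parents_present) *
               (1 - params$p_other_parent_died)) *
          .data$resid
    )
  keep <- setdiff(names(g), c("caregiver_type", "category", "g_loss"))
  out <- dplyr::select(wide, dplyr::all_of(keep), g_dedup)
  if (!is.null(orphan_new)) {
    jo <- intersect(setdiff(names(orphan_new), "new"), names(out))
    out <- out |>
      dplyr::left_join(
        orphan_new |>
          dplyr::group_by(dplyr::across(dplyr::all_of(jo))) |>
          dplyr::summarise(new = sum(new), .groups = "drop"),
        by = jo
      ) |>
      dplyr::mutate(l_new = dplyr::coalesce(new, 0) + g_dedup) |>
      dplyr::select(-new)
  }
  out
}

#' Combined caregiver-loss prevalence
#'
#' Adds to orphanhood prevalence the survival-discounted accrual of the
#' de-duplicated annual grandparent caregiver-loss contributions. Because
#' the grandparent contributions derive from cross-sectional data, the
#' survival product here starts at lag 0 (it includes the current-year
#' child survival factor), unlike the orphanhood accrual which starts at
#' lag 1.
#'
#' @param orphan_lifetime Orphanhood prevalence
#'   ([accumulate_prevalence()]) with columns `year`, `child_age`, shared
#'   strata and `lifetime`.
#' @param g_dedup_by_age De-duplicated grandparent caregiver loss by child
#'   age: columns `year`, `child_age`, strata, `g_dedup`, covering the 17
#'   years before each requested year.
#' @param child_hazards Single-age child hazards as in
#'   [accumulate_prevalence()].
#' @param years Years to report.
#' @return Tibble of strata plus `year`, `child_age`, `g_lifetime`,
#'   `lifetime` (orphanhood) and `l_lifetime` (combined).
#' @export
caregiver_prevalence <- function(orphan_lifetime, g_dedup_by_age,
                                 child_hazards, years) {
  gp <- cohort_accumulate(g_dedup_by_age, child_hazards, years,
                          start_j = 0, value_col = "g_dedup",
                          out_col = "g_lifetime")
  jn <- intersect(names(gp), setdiff(names(orphan_lifetime), "lifetime"))
  dplyr::full_join(orphan_lifetime, gp, by = jn) |>
    dplyr::mutate(
      lifetime = dplyr::coalesce(lifetime, 0),
      g_lifetime = dplyr::coalesce(.data$g_lifetime, 0),
      l_lifetime = lifetime + .data$g_lifetime
    )
}
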