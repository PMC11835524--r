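#' Read and validate a vital-statistics count table
#'
#' Reads a normalized long-format CSV/TSV and validates it against the
#' schema for its kind. Counts must be non-negative, stratum keys unique
#' (duplicates are an error, never summed), and suppressed cells carry a
#' flag instead of a count.
#'
#' Schemas (all columns lower case):
#' * `mortality`: year, age_band, sex, race_ethnicity, cause, count
#'   (optional `suppressed` logical, optional `state`); a `cause_code`
#'   column may stand in for `cause` before cause mapping.
#' * `natality`: year, parent_age_band, parent_sex, race_ethnicity, count
#'   (also accepted as age_band/sex; normalized to age_band/sex on read).
#' * `population`: year, age_band, sex, race_ethnicity, count.
#' * `child_survival`: birth_year, age (0-17), p_survive in \[0, 1\]
#'   (optional race_ethnicity).
#' * `cause_map`: source_code, scheme, target.
#' * `comparability`: cause, ratio (> 0), sd (>= 0).
#' * `caregiver_proportions`: year, sex, race_ethnicity, gamma_coreside,
#'   p_coreside_race, p_most_responsible, q_skip_gen (optional moe90_*).
#'
#' @param path Path to a delimited text file (delimiter sniffed from the
#'   extension: `.tsv` means tab, otherwise comma).
#' @param kind One of the schema names above.
#' @return A validated tibble. Row order is irrelevant to all downstream
#'   operations.
#' @export
load_vital_table <- function(path, kind) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  validate_vital_table(x, kind)
}

#' Validate an in-memory vital table
#'
#' @param x A data frame.
#' @param kind Schema name, see [load_vital_table()].
#' @return The validated tibble (invisibly unchanged apart from column
#'   normalization for natality).
#' @export
validate_vital_table <- function(x, kind) {
  kinds <- list(
    mortality = list(req = c("year", "age_band", "sex", "race_ethnicity",
                             "count"),
                     opt = c("cause", "cause_code", "suppressed", "state")),
    natality = list(req = c("year", "age_band", "sex", "race_ethnicity",
                            "count"),
                    opt = c("suppressed", "state")),
    population = list(req = c("year", "age_band", "sex", "race_ethnicity",
                              "count"),
                      opt = c("state", "suppressed")),
    child_survival = list(req = c("birth_year", "age", "p_survive"),
                          opt = "race_ethnicity"),
    child_mortality = list(req = c("year", "age", "race_ethnicity", "count"),
                           opt = c("sex", "state")),
    child_population = list(req = c("year", "age", "race_ethnicity", "count"),
                            opt = c("sex", "state")),
    cause_map = list(req = c("source_code", "target"), opt = "scheme"),
    comparability = list(req = c("cause", "ratio"), opt = "sd"),
    caregiver_proportions = list(
      req = c("year", "sex", "race_ethnicity", "gamma_coreside",
              "p_coreside_race", "p_most_responsible", "q_skip_gen"),
      opt = c("moe90_gamma_coreside", "moe90_p_coreside_race",
              "moe90_p_most_responsible", "moe90_q_skip_gen", "state"))
  )
  if (!kind %in% names(kinds)) {
    stop("unknown table kind: ", kind, call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (identical(kind, "natality")) {
    nm <- names(x)
    nm[nm == "parent_age_band"] <- "age_band"
    nm[nm == "parent_sex"] <- "sex"
    names(x) <- nm
  }
  sch <- kinds[[kind]]
  unknown <- setdiff(names(x), c(sch$req, sch$opt))
  if (length(unknown)) {
    stop("schema error: unknown column(s) for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(sch$req, names(x))
  if (kind == "mortality" &&
      !any(c("cause", "cause_code") %in% names(x))) {
    missing <- c(missing, "cause or cause_code")
  }
  if (length(missing)) {
    stop("schema error: missing column(s) for ", kind, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("count" %in% names(x)) {
    if (!"suppressed" %in% names(x)) x$suppressed <- FALSE
    x$suppressed[is.na(x$suppressed)] <- FALSE
    bad <- !x$suppressed & (is.na(x$count) | x$count < 0)
    if (any(bad)) {
      stop("schema error: negative or missing count in unsuppressed cell",
           call. = FALSE)
    }
    if (any(x$suppressed & !is.na(x$count))) {
      stop("schema error: suppressed cell carries a count", call. = FALSE)
    }
    if (all(!x$suppressed)) x$suppressed <- NULL
  }
  if ("p_survive" %in% names(x) &&
      any(x$p_survive < 0 | x$p_survive > 1, na.rm = TRUE)) {
    stop("schema error: p_survive outside [0, 1]", call. = FALSE)
  }
  if ("ratio" %in% names(x) && any(x$ratio <= 0, na.rm = TRUE)) {
    stop("configuration error: comparability ratio <= 0", call. = FALSE)
  }
  key <- intersect(
    c("year", "birth_year", "state", "age_band", "age", "sex",
      "race_ethnicity", "cause", "cause_code", "source_code", "scheme"),
    names(x)
  )
  if (length(key) && anyDuplicated(x[key])) {
    stop("duplication error: duplicated stratum key(s) in ", kind,
         " table (duplicates are never summed)", call. = FALSE)
  }
  if ("age_band" %in% names(x)) band_bounds(unique(x$age_band))
  x
}

#' Map causes of death to rankable caregiver-loss categories
#'
#' Aggregates death counts from raw ICD codes (or recode labels) to the
#' rankable caregiver-loss cause categories via a cause map. Codes absent
#' from the map fall to `"other"`. Totals are conserved exactly within
#' each (year, age band, sex, race/ethnicity) stratum.
#'
#' @param deaths Mortality tibble with a `cause_code` column.
#' @param cause_map Tibble with columns `source_code`, `target` (and
#'   optionally `scheme`); each source code must map to exactly one target.
#' @return Mortality tibble with a `cause` column, counts aggregated to
#'   targets.
#' @export
map_causes <- function(deaths, cause_map) {
  stopifnot("cause_code" %in% names(deaths))
  dup <- cause_map |>
    dplyr::distinct(source_code, target) |>
    dplyr::count(source_code) |>
    dplyr::filter(n > 1)
  if (nrow(dup)) {
    stop("configuration error: source code(s) mapped to multiple targets: ",
         paste(dup$source_code, collapse = ", "), call. = FALSE)
  }
  keys <- setdiff(names(deaths), c("cause_code", "count", "suppressed"))
  deaths |>
    dplyr::left_join(
      dplyr::distinct(cause_map, source_code, target),
      by = c(cause_code = "source_code")
    ) |>
    dplyr::mutate(cause = dplyr::coalesce(target, "other")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cause")))) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
}

#' Standardize race and ethnicity reporting
#'
#' Maps raw race codes and Hispanic-origin flags to the five standardized
#' race and ethnicity categories. Any record of Hispanic origin is
#' `"Hispanic"` regardless of race; records of more than one race are the
#' `"EXCLUDED"` sentinel and must be dropped (with logging) from all
#' downstream totals.
#'
#' @param race_code Character vector of raw race codes.
#' @param hispanic_origin Logical (or `"yes"`/`"no"`) vector.
#' @param race_map Tibble with columns `race_code`, `category` mapping the
#'   non-Hispanic raw vocabulary; defaults to [default_race_map()].
#' @return Character vector of standardized categories or `"EXCLUDED"`.
#' @examples
#' standardize_race("white", FALSE)
#' standardize_race("black", TRUE) # Hispanic
#' @export
standardize_race <- function(race_code, hispanic_origin,
                             race_map = default_race_map()) {
  if (is.character(hispanic_origin)) {
    hispanic_origin <- tolower(hispanic_origin) %in%
      c("yes", "y", "true", "hispanic")
  }
  idx <- match(race_code, race_map$race_code)
  if (any(is.na(idx) & !hispanic_origin)) {
    stop("configuration error: unmapped race code(s): ",
         paste(unique(race_code[is.na(idx) & !hispanic_origin]),
               collapse = ", "),
         call. = FALSE)
  }
  out <- race_map$category[idx]
  out[hispanic_origin] <- "Hispanic"
  out
}

#' @rdname standardize_race
#' @export
default_race_map <- function() {
  tibble::tribble(
    ~race_code, ~category,
    "white", "non-Hispanic white",
    "black", "non-Hispanic Black",
    "american_indian_alaska_native", "non-Hispanic American Indian or Alaska Native",
    "asian_pacific_islander", "non-Hispanic Asian or Pacific Islander",
    "asian", "non-Hispanic Asian or Pacific Islander",
    "pacific_islander", "non-Hispanic Asian or Pacific Islander",
    "more_than_one", "EXCLUDED",
    "other", "EXCLUDED"
  )
}

#' Drop EXCLUDED race records, logging the dropped count
#'
#' @param x Tibble with a `race_ethnicity` column.
#' @return `x` without `"EXCLUDED"` rows; the number of dropped records is
#'   reported as a message.
#' @export
drop_excluded_race <- function(x) {
  n_drop <- if ("count" %in% names(x)) {
    sum(x$count[x$race_ethnicity == "EXCLUDED"], na.rm = TRUE)
  } else {
    sum(x$race_ethnicity == "EXCLUDED")
  }
  if (n_drop > 0) {
    message("dropping ", n_drop, " record(s) with EXCLUDED race/ethnicity")
  }
  dplyr::filter(x, race_ethnicity != "EXCLUDED")
}

#' Apply ICD-9 to ICD-10 comparability ratios
#'
#' Multiplies cause-specific death counts in the ICD-9-coded years by their
#' comparability ratio, harmonizing them to ICD-10 cause definitions.
#' Causes without a published ratio are treated as ratio 1 (unchanged).
#' Counts become real-valued downstream of this step and are deliberately
#' not re-rounded.
#'
#' @param deaths Mortality tibble with a `cause` column.
#' @param ratios Tibble with columns `cause`, `ratio` (> 0) and optionally
#'   `sd`.
#' @param years Integer vector of ICD-9-coded years to adjust (the study
#'   design uses years before 1999).
#' @return Mortality tibble with adjusted counts.
#' @export
apply_comparability <- function(deaths, ratios, years) {
  if (any(ratios$ratio <= 0)) {
    stop("configuration error: comparability ratio <= 0", call. = FALSE)
  }
  deaths |>
    dplyr::left_join(dplyr::select(ratios, cause, ratio), by = "cause") |>
    dplyr::mutate(
      ratio = dplyr::coalesce(ratio, 1),
      count = ifelse(year %in% years, count * ratio, count)
    ) |>
    dplyr::select(-ratio)
}

#' Redistribute counts of one year across races by a donor year's composition
#'
#' Optional backfill step for years whose records lack race/ethnicity:
#' counts of `target_year` (unstratified by race) are allocated across
#' races proportional to the donor year's composition within each
#' (age band, sex, cause) stratum.
#'
#' @param counts Mortality tibble where `target_year` rows have
#'   `race_ethnicity = NA` and donor-year rows are race-stratified.
#' @param target_year,donor_year Calendar years.
#' @return Tibble with `target_year` rows split across races.
#' @export
backfill_race_composition <- function(counts, target_year, donor_year) {
  strata <- intersect(c("age_band", "sex", "cause", "state"), names(counts))
  comp <- counts |>
    dplyr::filter(year == donor_year, !is.na(race_ethnicity)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::mutate(prop = count / sum(count)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(strata), race_ethnicity, prop)
  tgt <- counts |> dplyr::filter(year == target_year, is.na(race_ethnicity))
  rest <- counts |>
    dplyr::filter(!(year == target_year & is.na(race_ethnicity)))
  filled <- tgt |>
    dplyr::select(-race_ethnicity) |>
    dplyr::inner_join(comp, by = strata) |>
    dplyr::mutate(count = count * prop) |>
    dplyr::select(-prop)
  dplyr::bind_rows(rest, filled)
}
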