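#' Published national median estimates of US caregiver loss
#'
#' National median estimates of annual incidence and lifetime prevalence
#' of orphanhood and of primary and secondary grandparent caregiver loss
#' among US children for 2000, 2019, 2020 and 2021, as published in the
#' national all-cause caregiver-loss literature. Shipped as a small CSV
#' and used in worked examples of the summary arithmetic (shares and
#' percent changes between years).
#'
#' @return Tibble `measure`, `statistic` (`incidence`/`prevalence`),
#'   `year`, `count`.
#' @examples
#' m <- published_medians()
#' inc <- subset(m, statistic == "incidence" & measure == "total")
#' percent_change(inc$count[inc$year == 2000], inc$count[inc$year == 2021])
#' @export
published_medians <- function() {
  readr::read_csv(
    system.file("extdata", "us_caregiver_loss_published_medians.csv",
                package = "kinloss"),
    show_col_types = FALSE, progress = FALSE
  )
}
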