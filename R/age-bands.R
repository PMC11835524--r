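#' Age-band utilities
#'
#' Age strata are encoded as character labels: closed five-year bands
#' (`"15-19"`), an open terminal band (`"85+"`), or single years of age
#' (`"3"`). These helpers parse labels, compute band midpoints and widths,
#' and assign single ages to a band set.
#'
#' The midpoint of a closed band `[lo, hi]` is `(lo + hi + 1) / 2`, the
#' centre of the continuous age interval `[lo, hi + 1)`; the open band
#' `"85+"` is given the midpoint 87.5, i.e. it is treated as five years
#' wide for hazard purposes.
#'
#' @param band Character vector of band labels.
#' @return `band_bounds()` returns a tibble with columns `band`, `lo`, `hi`
#'   (`hi` is `Inf` for open bands); `band_midpoint()` and `band_width()`
#'   return numeric vectors.
#' @examples
#' band_bounds(c("15-19", "85+", "0"))
#' band_midpoint("15-19") # 17.5
#' @export
band_bounds <- function(band) {
  band <- as.character(band)
  open <- grepl("^[0-9]+\\+$", band)
  rng <- grepl("^[0-9]+-[0-9]+$", band)
  single <- grepl("^[0-9]+$", band)
  bad <- !(open | rng | single)
  if (any(bad)) {
    stop("unparseable age band label(s): ",
      paste(unique(band[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  lo <- as.numeric(sub("^([0-9]+).*$", "\\1", band))
  hi <- lo
  hi[rng] <- as.numeric(sub("^[0-9]+-([0-9]+)$", "\\1", band[rng]))
  hi[open] <- Inf
  if (any(hi < lo)) stop("age band with hi < lo", call. = FALSE)
  tibble::tibble(band = band, lo = lo, hi = hi)
}

#' @rdname band_bounds
#' @export
band_midpoint <- function(band) {
  bb <- band_bounds(band)
  ifelse(is.finite(bb$hi), (bb$lo + bb$hi + 1) / 2, bb$lo + 2.5)
}

#' @rdname band_bounds
#' @export
band_width <- function(band) {
  bb <- band_bounds(band)
  ifelse(is.finite(bb$hi), bb$hi - bb$lo + 1, 5)
}

#' Assign single ages to a band set
#'
#' @param age Integer vector of single ages.
#' @param bands Character vector of non-overlapping band labels.
#' @return Character vector of band labels (`NA` where no band covers the
#'   age).
#' @examples
#' band_for_age(c(14, 23, 90), adult_bands())
#' @export
band_for_age <- function(age, bands) {
  bb <- band_bounds(bands)
  bb <- bb[order(bb$lo), ]
  idx <- findInterval(age, bb$lo)
  out <- rep(NA_character_, length(age))
  ok <- idx >= 1
  ok[ok] <- age[ok] <= bb$hi[idx[ok]]
  out[ok] <- bb$band[idx[ok]]
  out
}

#' Standard band sets
#'
#' Adult mortality/population bands run 15-19 through 80-84 plus 85+;
#' maternal fertility bands 15-19 through 45-49; paternal fertility bands
#' 15-19 through 50-54 plus 55-77, matching the maximum parental ages at
#' the birth of a child (mothers 49, fathers 77).
#'
#' @return Character vector of band labels.
#' @export
adult_bands <- function() {
  c(paste(seq(15, 80, 5), seq(19, 84, 5), sep = "-"), "85+")
}

#' @rdname adult_bands
#' @export
mother_bands <- function() {
  paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
}

#' @rdname adult_bands
#' @export
father_bands <- function() {
  c(paste(seq(15, 50, 5), seq(19, 54, 5), sep = "-"), "55-77")
}

#' @rdname adult_bands
#' @param sex `"female"` or `"male"`.
#' @export
fertility_bands <- function(sex) {
  stopifnot(sex %in% c("female", "male"))
  if (identical(sex, "female")) mother_bands() else father_bands()
}

# Maximum single age of a parent of a child aged 0-17: 49 + 17 and 77 + 17.
parent_age_range <- function(sex) {
  if (identical(sex, "female")) 15:66 else 15:94
}
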