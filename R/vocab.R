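#' Domain vocabulary: FIGO stages, age bands and screening categories
#'
#' The analysis is indexed throughout by three vocabularies: FIGO stage at
#' diagnosis (1A < 1B < 2 < 3plus, plus an unordered \code{"unknown"}),
#' half-open age bands \code{[lower, upper)} in decimal years, and an
#' age-dependent screening-regularity category derived from the maximum
#' interval between adequate smears.
#'
#' @section Age bands:
#' Three band systems are used. \emph{Diagnosis} bands partition
#' \code{[25.5, 80)}: 25.5-34, 35-49, 50-64, 65-79. \emph{Odds-ratio} bands
#' pool 35-49 with 50-64 (the published strata): 25.5-34, 35-64, 65-79.
#' \emph{Survival} bands split 65-79 into 65-69 and 70-79.
#' \emph{Death} bands are diagnosis bands with the upper edge shifted 5 years
#' (deaths within 5 years of diagnosis): 25-39, 40-54, 55-69, 70-84.
#'
#' @name vocab
NULL

#' @rdname vocab
#' @param include_unknown also return the \code{"unknown"} level
#' @return \code{stage_levels}: character vector of stage codes in severity order.
#' @export
stage_levels <- function(include_unknown = FALSE) {
  s <- c("1A", "1B", "2", "3plus")
  if (include_unknown) c(s, "unknown") else s
}

#' @rdname vocab
#' @param age_band an age-band label, or \code{NULL} for the full set
#' @return \code{category_levels}: screening categories in ascending regularity
#'   (\code{not_screened} first, the referent). Ages 25.5-34 have no
#'   \code{very_irregular} level.
#' @export
category_levels <- function(age_band = NULL) {
  full <- c("not_screened", "very_irregular", "irregular", "regular")
  if (!is.null(age_band) && age_band %in% c("25.5-34"))
    return(c("not_screened", "irregular", "regular"))
  full
}

#' @rdname vocab
#' @param category character vector of screening categories
#' @return \code{category_score}: integer ordinal score, 0 = not screened,
#'   ascending regularity (used by the linear-trend model).
#' @export
category_score <- function(category) {
  match(category, c("not_screened", "very_irregular", "irregular", "regular")) - 1L
}

band_frame <- function(label, lower, upper) {
  data.frame(band = label, lower = lower, upper = upper, stringsAsFactors = FALSE)
}

#' @rdname vocab
#' @return \code{diagnosis_bands}: data.frame of half-open diagnosis age bands.
#' @export
diagnosis_bands <- function() {
  band_frame(c("25.5-34", "35-49", "50-64", "65-79"),
             c(25.5, 35, 50, 65), c(35, 50, 65, 80))
}

#' @rdname vocab
#' @return \code{or_bands}: the pooled strata in which odds ratios are reported.
#' @export
or_bands <- function() {
  band_frame(c("25.5-34", "35-64", "65-79"), c(25.5, 35, 65), c(35, 65, 80))
}

#' @rdname vocab
#' @return \code{survival_bands}: age bands of the case-fatality table.
#' @export
survival_bands <- function() {
  band_frame(c("25.5-34", "35-49", "50-64", "65-69", "70-79"),
             c(25.5, 35, 50, 65, 70), c(35, 50, 65, 70, 80))
}

#' Locate an age in a band system
#'
#' @param age decimal age in years (365.25-day years)
#' @param bands a band data.frame from [diagnosis_bands()] or [or_bands()]
#' @return the band label; error if the age falls outside every band
#' @export
age_band_of <- function(age, bands = diagnosis_bands()) {
  i <- findInterval(age, c(bands$lower, bands$upper[nrow(bands)]),
                    rightmost.closed = FALSE)
  if (any(i < 1 | i > nrow(bands)))
    stop("age ", paste(age[i < 1 | i > nrow(bands)], collapse = ", "),
         " outside the supported bands [25.5, 80)")
  bands$band[i]
}

#' Map a diagnosis age band to its band of death
#'
#' Deaths within 5 years of diagnosis fall in an age-at-death interval whose
#' upper edge is 5 years beyond the diagnosis band (25-34 at diagnosis maps to
#' 25-39 at death, 35-49 to 40-54, and so on).
#'
#' @param diag_band diagnosis band label(s); \code{"25-34"} and \code{"25.5-34"}
#'   are synonyms (the projection includes women diagnosed at 25-25.5)
#' @return death-band label(s)
#' @export
death_band_for <- function(diag_band) {
  map <- c("25-34" = "25-39", "25.5-34" = "25-39", "35-49" = "40-54",
           "50-64" = "55-69", "65-79" = "70-84")
  out <- map[diag_band]
  if (anyNA(out)) stop("no death band for diagnosis band: ",
                       paste(diag_band[is.na(out)], collapse = ", "))
  unname(out)
}

DAYS_PER_YEAR <- 365.25

#' Decimal age at a date
#'
#' @param date,birth_date \code{Date} vectors
#' @return age in 365.25-day years
#' @export
age_at <- function(date, birth_date) {
  as.numeric(as.Date(date) - as.Date(birth_date)) / DAYS_PER_YEAR
}
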