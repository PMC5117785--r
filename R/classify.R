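#' Screening window for a woman at her reference date
#'
#' The window over which the maximum screening interval is measured depends on
#' age at the reference (diagnosis) date:
#' ages 35-64 look back \code{window_years} (default 15) years from the
#' reference date; ages 65+ consider screening at ages 50-64 regardless of the
#' reference date; ages 25.5-34 consider screening from age 22.5 up to the
#' last 3-year age-slice boundary at or below current age (25.5, 28.5 or 31.5).
#' Women under 25.5 at reference are outside the analysis.
#'
#' Windows are expressed in decimal age (years since birth, 365.25-day years),
#' which makes the two window styles commensurable.
#'
#' @param age_at_reference decimal age at the reference date (>= 25.5)
#' @param window_years lookback for ages 35-64 (sensitivity analyses use 12 or 8)
#' @return list with \code{start}, \code{end} (decimal ages) and \code{rule},
#'   one of \code{"young"}, \code{"lookback"}, \code{"age50_64"}
#' @export
screening_window <- function(age_at_reference, window_years = 15) {
  a <- age_at_reference
  if (is.na(a) || a < 25.5)
    stop("screening categories are undefined under age 25.5 (age ", a, ")")
  if (a < 35) {
    end <- if (a < 28.5) 25.5 else if (a < 31.5) 28.5 else 31.5
    list(start = 22.5, end = end, rule = "young")
  } else if (a < 65) {
    list(start = a - window_years, end = a, rule = "lookback")
  } else {
    list(start = 50, end = 65, rule = "age50_64")
  }
}

#' Maximum interval with no adequate smear
#'
#' The longest period inside the screening window containing no adequate
#' smear: the largest of the gap from window start to the first adequate smear
#' in the window, the gaps between consecutive adequate smears, and the gap
#' from the last adequate smear to the window end. Inadequate smears are
#' ignored; with no adequate smear in the window the whole window length is
#' returned.
#'
#' @param smear_ages decimal ages at smear tests
#' @param adequate logical, same length; inadequate tests are dropped
#' @param window list with \code{start}, \code{end} from [screening_window()]
#' @return maximum gap in years
#' @export
max_adequate_interval <- function(smear_ages, adequate = rep(TRUE, length(smear_ages)),
                                  window) {
  stopifnot(window$start < window$end)
  s <- sort(smear_ages[adequate & smear_ages >= window$start &
                         smear_ages <= window$end])
  if (length(s) == 0) return(window$end - window$start)
  max(diff(c(window$start, s, window$end)))
}

regular_cutoff <- function(age_at_reference) {
  # keyed to age at the reference date, not age at each smear
  if (age_at_reference < 50) 3.5 else 5.5
}

#' Assign the screening-regularity category
#'
#' Ages 35-64: \code{regular} if the maximum interval is <= 3.5 years (ages
#' 35-49) or <= 5.5 years (50-64); \code{irregular} if <= 7.5; then
#' \code{very_irregular} if <= 13; otherwise \code{not_screened}. Ages 65+ use
#' the 50-64 window with the 5.5 / 7.5 / 13 cut-offs. Ties at a cut-off go to
#' the more regular category. Ages 25.5-34: \code{regular} iff every required
#' 3-year age slice (22.5-25.5; plus 25.5-28.5 from age 28.5; plus 28.5-31.5
#' from age 31.5) contains an adequate smear, \code{irregular} iff there is an
#' adequate smear in the window but not in every slice, else
#' \code{not_screened}.
#'
#' @inheritParams max_adequate_interval
#' @param age_at_reference decimal age at the reference date (>= 25.5)
#' @param window_years lookback length for ages 35-64
#' @return list with \code{category}, \code{max_interval} (NA for the
#'   slice-based 25.5-34 rule) and \code{window}
#' @export
classify_screening <- function(age_at_reference, smear_ages,
                               adequate = rep(TRUE, length(smear_ages)),
                               window_years = 15) {
  w <- screening_window(age_at_reference, window_years)
  if (w$rule == "young") {
    slice_lo <- c(22.5, 25.5, 28.5)
    n_slices <- if (age_at_reference < 28.5) 1 else if (age_at_reference < 31.5) 2 else 3
    a <- smear_ages[adequate]
    in_window <- a >= w$start & a <= w$end
    covered <- vapply(seq_len(n_slices), function(k)
      any(a >= slice_lo[k] & a < slice_lo[k] + 3), logical(1))
    cat <- if (all(covered)) "regular"
           else if (any(in_window)) "irregular" else "not_screened"
    return(list(category = cat, max_interval = NA_real_, window = w))
  }
  gap <- max_adequate_interval(smear_ages, adequate, w)
  c1 <- if (w$rule == "age50_64") 5.5 else regular_cutoff(age_at_reference)
  cat <- if (gap <= c1) "regular"
         else if (gap <= 7.5) "irregular"
         else if (gap <= 13) "very_irregular" else "not_screened"
  list(category = cat, max_interval = gap, window = w)
}

#' Classify every woman in a cohort
#'
#' Joins the smear file to the women file, converts dates to decimal ages and
#' applies [classify_screening()] per woman.
#'
#' @param women data.frame with \code{woman_id}, \code{birth_date},
#'   \code{reference_date} (Dates or ISO-8601 strings)
#' @param smears data.frame with \code{woman_id}, \code{date}, \code{adequate}
#' @param window_years lookback for ages 35-64
#' @return data.frame \code{woman_id}, \code{max_interval_years}, \code{category}
#' @export
classify_cohort <- function(women, smears, window_years = 15) {
  women$birth_date <- as.Date(women$birth_date)
  women$reference_date <- as.Date(women$reference_date)
  smears$date <- as.Date(smears$date)
  by_woman <- split(seq_len(nrow(smears)), smears$woman_id)
  out <- lapply(seq_len(nrow(women)), function(i) {
    wid <- women$woman_id[i]
    idx <- by_woman[[wid]]
    ages <- if (is.null(idx)) numeric(0)
            else age_at(smears$date[idx], women$birth_date[i])
    adeq <- if (is.null(idx)) logical(0) else as.logical(smears$adequate[idx])
    cl <- classify_screening(age_at(women$reference_date[i], women$birth_date[i]),
                             ages, adeq, window_years)
    data.frame(woman_id = wid, max_interval_years = cl$max_interval,
               category = cl$category, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
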