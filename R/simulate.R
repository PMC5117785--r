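#' Configuration for the synthetic matched cohort
#'
#' Encodes the generative structure the estimators assume: age-matched
#' 1-case : 1-2-control sets, a control screening-category distribution per
#' diagnosis age band, stage-specific multiplicative odds-ratio effects of
#' screening on the case's category, a missing-stage fraction, and smear
#' histories constructed to realise each woman's category under the
#' age-dependent interval rules.
#'
#' Defaults are the study conditions of the England audit: the age
#' distribution of cases (29\% at 25.5-34, 39\% at 35-49, 19.5\% at 50-64,
#' 12.5\% at 65-79), true odds ratios and never-screened stage distributions
#' taken from the packaged \code{england_audit} tables, a missing-stage
#' fraction of 1579/11619, and 1\% single-control sets.
#'
#' @param n_sets number of matched sets
#' @param seed RNG seed; a fixed seed reproduces the cohort exactly
#' @param age_distribution named probabilities over [diagnosis_bands()]
#' @param control_category_prevalence named list, one probability vector over
#'   screening categories per diagnosis band
#' @param true_or data.frame \code{age_band} (odds-ratio band), \code{stage},
#'   \code{category}, \code{or}; the referent category has OR 1
#' @param stage_distribution named list, per odds-ratio band, probabilities
#'   over stages among never-screened women
#' @param missing_stage_fraction probability a case's stage is recorded unknown
#' @param single_control_fraction probability a set has one control only
#' @param window_years lookback window for ages 35-64
#' @return a \code{sim_config} list
#' @export
sim_config <- function(n_sets = 1000,
                       seed = 1,
                       age_distribution = c("25.5-34" = 0.29, "35-49" = 0.39,
                                            "50-64" = 0.195, "65-79" = 0.125),
                       control_category_prevalence = default_control_prevalence(),
                       true_or = NULL,
                       stage_distribution = NULL,
                       missing_stage_fraction = 1579 / 11619,
                       single_control_fraction = 0.01,
                       window_years = 15) {
  fx <- NULL
  if (is.null(true_or)) {
    fx <- load_fixture_tables()
    true_or <- fx$ors[, c("age_band", "stage", "category", "or")]
  }
  if (is.null(stage_distribution)) {
    if (is.null(fx)) fx <- load_fixture_tables()
    ns <- fx$counts[fx$counts$stage != "unknown" &
                      fx$counts$category == "not_screened", ]
    stage_distribution <- lapply(split(ns, ns$age_band), function(d) {
      p <- d$count / sum(d$count)
      names(p) <- d$stage
      p
    })
  }
  stopifnot(abs(sum(age_distribution) - 1) < 1e-8)
  for (p in control_category_prevalence) stopifnot(abs(sum(p) - 1) < 1e-8)
  for (p in stage_distribution) stopifnot(abs(sum(p) - 1) < 1e-8)
  stopifnot(all(true_or$or[true_or$category == "not_screened"] == 1))
  structure(list(n_sets = n_sets, seed = seed,
                 age_distribution = age_distribution,
                 control_category_prevalence = control_category_prevalence,
                 true_or = true_or, stage_distribution = stage_distribution,
                 missing_stage_fraction = missing_stage_fraction,
                 single_control_fraction = single_control_fraction,
                 window_years = window_years),
            class = "sim_config")
}

#' @rdname sim_config
#' @details \code{default_control_prevalence()} gives a realistic control mix:
#'   most women of screening age attend regularly, attendance tails off in the
#'   cohorts screened at ages 50-64 before 2007.
#' @export
default_control_prevalence <- function() {
  list("25.5-34" = c(not_screened = 0.15, irregular = 0.25, regular = 0.60),
       "35-49" = c(not_screened = 0.08, very_irregular = 0.12,
                   irregular = 0.15, regular = 0.65),
       "50-64" = c(not_screened = 0.10, very_irregular = 0.13,
                   irregular = 0.12, regular = 0.65),
       "65-79" = c(not_screened = 0.30, very_irregular = 0.14,
                   irregular = 0.11, regular = 0.45))
}

or_band_for <- function(diag_band) {
  c("25.5-34" = "25.5-34", "35-49" = "35-64", "50-64" = "35-64",
    "65-79" = "65-79")[[diag_band]]
}

# categories that a smear history can realise at this reference age
realisable_categories <- function(age, or_band) {
  lv <- category_levels(or_band)
  # under age 28.5 the single required slice makes "irregular" unreachable
  if (or_band == "25.5-34" && age < 28.5) lv <- setdiff(lv, "irregular")
  lv
}

# smear ages (plus adequacy) that classify_screening() maps back to `category`
realise_history <- function(category, age, or_band, window_years) {
  w <- screening_window(age, window_years)
  ages <- numeric(0)
  if (w$rule == "young") {
    slice_lo <- c(22.5, 25.5, 28.5)
    n_slices <- if (age < 28.5) 1 else if (age < 31.5) 2 else 3
    if (category == "regular") {
      ages <- slice_lo[seq_len(n_slices)] + stats::runif(n_slices, 0.3, 2.7)
    } else if (category == "irregular") {
      if (n_slices < 2)
        stop("irregular is unrealisable under age 28.5 (band 25.5-34)")
      ages <- 22.5 + stats::runif(1, 0.3, 2.7)  # first slice only
    }
  } else {
    c1 <- if (w$rule == "age50_64") 5.5 else regular_cutoff(age)
    len <- w$end - w$start
    d <- switch(category,
      regular        = stats::runif(1, min(1, c1 / 2), c1 - 0.1),
      irregular      = stats::runif(1, c1 + 0.1, 7.4),
      very_irregular = stats::runif(1, 7.6, 12.9),
      not_screened   = if (stats::runif(1) < 0.5) NA else
                         stats::runif(1, 13.2, len - 0.2))
    if (!is.na(d)) ages <- seq(w$start + d, w$end, by = d)
  }
  adequate <- rep(TRUE, length(ages))
  if (stats::runif(1) < 0.25) {            # inadequate tests must be ignored
    ages <- c(ages, stats::runif(1, w$start, w$end))
    adequate <- c(adequate, FALSE)
  }
  list(ages = ages, adequate = adequate)
}

#' Simulate a matched case-control cohort with smear histories
#'
#' For each set: an age band and exact age are drawn; 1-2 controls are matched
#' on age (within half a year, never across a classification boundary); control
#' categories follow the band's prevalence; the case's stage is drawn from the
#' never-screened stage distribution and its category from the prevalence
#' tilted by the true odds ratios, \eqn{P(j | stage\ s) \propto p_j
#' \mathrm{OR}_{sj}}, so that conditional logistic regression on the output
#' recovers the configured ORs. Stage is then blanked to \code{"unknown"} with
#' the configured probability. Finally, dated smear records are constructed to
#' realise each woman's category exactly under the interval rules, with
#' jittered spacing and occasional inadequate tests.
#'
#' @param config a [sim_config()]
#' @return list of class \code{sim_cohort}: \code{women} (one row per woman,
#'   including the generator's ground-truth \code{true_category} and
#'   \code{true_stage}), \code{smears}, and the \code{config}
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dbands <- diagnosis_bands()
  ref_origin <- as.Date("2007-04-01")
  ref_span <- as.numeric(as.Date("2013-03-31") - ref_origin)
  women <- vector("list", config$n_sets)
  smears <- vector("list", config$n_sets)
  for (k in seq_len(config$n_sets)) {
    band <- sample(names(config$age_distribution), 1,
                   prob = config$age_distribution)
    b <- dbands[dbands$band == band, ]
    age <- stats::runif(1, b$lower + 0.01, b$upper - 0.01)
    orb <- or_band_for(band)
    support <- realisable_categories(age, orb)
    prev <- config$control_category_prevalence[[band]][support]
    prev <- prev / sum(prev)
    # case stage, then category tilted by the stage's odds ratios
    stages <- config$stage_distribution[[orb]]
    true_stage <- sample(names(stages), 1, prob = stages)
    ors <- vapply(support, function(j)
      table_cell(config$true_or, "or", age_band = orb, stage = true_stage,
                 category = j), numeric(1))
    case_cat <- sample(support, 1, prob = prev * ors)
    rec_stage <- if (stats::runif(1) < config$missing_stage_fraction)
      "unknown" else true_stage
    n_controls <- if (stats::runif(1) < config$single_control_fraction) 1L else 2L
    # controls: age-matched within the same band and classification support
    lo <- max(b$lower + 0.01, if (orb == "25.5-34" && age >= 28.5) 28.51 else 0)
    hi <- min(b$upper - 0.01, if (orb == "25.5-34" && age < 28.5) 28.49 else Inf)
    ctrl_ages <- pmin(pmax(age + stats::runif(n_controls, -0.5, 0.5), lo), hi)
    ctrl_cats <- sample(support, n_controls, replace = TRUE, prob = prev)
    ref_date <- ref_origin + floor(stats::runif(1) * ref_span)
    set_ages <- c(age, ctrl_ages)
    set_cats <- c(case_cat, ctrl_cats)
    n <- n_controls + 1L
    sid <- sprintf("S%05d", k)
    wid <- sprintf("W%05d_%d", k, seq_len(n))
    birth <- ref_date - round(set_ages * DAYS_PER_YEAR)
    hist <- lapply(seq_len(n), function(m)
      realise_history(set_cats[m], age_at(ref_date, birth[m]), orb,
                      config$window_years))
    women[[k]] <- data.frame(
      woman_id = wid, set_id = sid, is_case = c(TRUE, rep(FALSE, n_controls)),
      birth_date = birth, reference_date = ref_date,
      stage = c(rec_stage, rep(NA_character_, n_controls)),
      age_band = band, true_stage = c(true_stage, rep(NA_character_, n_controls)),
      true_category = set_cats, stringsAsFactors = FALSE)
    ns <- vapply(hist, function(h) length(h$ages), integer(1))
    if (sum(ns) > 0)
      smears[[k]] <- data.frame(
        woman_id = rep(wid, ns),
        date = birth[rep(seq_len(n), ns)] +
          round(unlist(lapply(hist, `[[`, "ages")) * DAYS_PER_YEAR),
        adequate = unlist(lapply(hist, `[[`, "adequate")))
  }
  women <- do.call(rbind, women)
  smears <- do.call(rbind, smears[!vapply(smears, is.null, logical(1))])
  smears <- smears[order(smears$woman_id, smears$date), ]
  rownames(women) <- rownames(smears) <- NULL
  structure(list(women = women, smears = smears, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(unique(x$women$set_id)), " matched sets, ",
      nrow(x$women), " women, ", nrow(x$smears), " smear records (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a cohort as CSV files
#'
#' \code{women.csv} and \code{smears.csv} with ISO-8601 dates; the round trip
#' is lossless.
#'
#' @param cohort a \code{sim_cohort} (or a compatible list with \code{women}
#'   and \code{smears})
#' @param dir output directory (created if needed)
#' @return \code{write_cohort}: the directory, invisibly;
#'   \code{read_cohort}: a list with \code{women} and \code{smears}
#' @export
write_cohort <- function(cohort, dir) {
  if (anyDuplicated(cohort$women$woman_id))
    stop("duplicate woman_id in cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$women
  w$birth_date <- format(as.Date(w$birth_date))
  w$reference_date <- format(as.Date(w$reference_date))
  utils::write.csv(w, file.path(dir, "women.csv"), row.names = FALSE)
  s <- cohort$smears
  s$date <- format(as.Date(s$date))
  utils::write.csv(s, file.path(dir, "smears.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  w <- utils::read.csv(file.path(dir, "women.csv"), stringsAsFactors = FALSE)
  s <- utils::read.csv(file.path(dir, "smears.csv"), stringsAsFactors = FALSE)
  w$birth_date <- as.Date(w$birth_date)
  w$reference_date <- as.Date(w$reference_date)
  s$date <- as.Date(s$date)
  list(women = w, smears = s)
}
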