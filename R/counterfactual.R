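#' Counterfactual stage-specific cancer counts
#'
#' Divides each observed cell count by its odds ratio to recover the cancers
#' that would have been diagnosed had those women never been screened,
#' \eqn{\sum_j N_{ij} / \mathrm{OR}_{ij}} per (age band, stage); the
#' never-screened referent has OR 1. Scenarios: \code{"current"} returns the
#' counts unchanged; \code{"no_screening"} collapses every cell to the
#' never-screened category; \code{"all_regular"} further multiplies by the
#' regular-screening odds ratio, putting everyone in the regular category.
#'
#' @param counts a [case_count_table] with no unknown-stage rows (see
#'   [reallocate_missing()])
#' @param ors an [or_table] covering every (band, stage, category) with
#'   positive count
#' @param scenario counterfactual to project
#' @return a [case_count_table]; under the counterfactuals every row carries
#'   the scenario's single category
#' @export
counterfactual_cancers <- function(counts, ors,
                                   scenario = c("no_screening", "current",
                                                "all_regular")) {
  scenario <- match.arg(scenario)
  counts <- case_count_table(counts)
  if (any(counts$stage == "unknown"))
    stop("reallocate unknown-stage cases before projecting")
  if (scenario == "current") return(counts)
  out <- list()
  for (band in unique(counts$age_band)) {
    for (s in unique(counts$stage[counts$age_band == band])) {
      i <- counts$age_band == band & counts$stage == s
      n <- counts$count[i]
      or <- vapply(counts$category[i], function(j)
        table_cell(ors, "or", age_band = band, stage = s, category = j),
        numeric(1))
      if (any(is.na(or) & n > 0))
        stop("missing odds ratio for a populated cell in band ", band,
             ", stage ", s)
      if (any(or == 0, na.rm = TRUE)) stop("odds ratio of zero in band ", band)
      base <- sum(n / or)                       # cancers absent screening
      if (scenario == "no_screening") {
        val <- base; catg <- "not_screened"
      } else {
        or_reg <- table_cell(ors, "or", age_band = band, stage = s,
                             category = "regular")
        val <- base * or_reg; catg <- "regular"
      }
      out[[paste(band, s)]] <- data.frame(age_band = band, stage = s,
                                          category = catg, count = val,
                                          stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  case_count_table(tab)
}

#' Collapse the case-fatality table onto coarser age bands
#'
#' The odds ratios are reported in pooled bands (35-64, 65-79) while case
#' fatality is tabulated in finer bands; each pooled band's fatality is the
#' (by default unweighted) mean of its sub-bands, per stage.
#'
#' @param fatality a [fatality_table] on [survival_bands()]
#' @param bands target band labels (default the odds-ratio bands)
#' @param weights optional named list: per target band, weights over its
#'   sub-bands (e.g. case counts); default equal weights
#' @return a [fatality_table] on the target bands
#' @export
collapse_fatality <- function(fatality, bands = or_bands()$band,
                              weights = NULL) {
  members <- list("25.5-34" = "25.5-34", "35-49" = "35-49", "50-64" = "50-64",
                  "35-64" = c("35-49", "50-64"),
                  "65-79" = c("65-69", "70-79"))
  out <- list()
  for (b in bands) {
    sub <- members[[b]]
    if (is.null(sub)) stop("no sub-band mapping for band ", b)
    w <- weights[[b]] %||% setNames(rep(1, length(sub)), sub)
    w <- w[sub] / sum(w[sub])
    for (s in unique(fatality$stage)) {
      rho <- vapply(sub, function(a)
        table_cell(fatality, "rho", age_band = a, stage = s), numeric(1))
      out[[paste(b, s)]] <- data.frame(age_band = b, stage = s,
                                       rho = sum(w * rho),
                                       stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  fatality_table(tab)
}

# fatality for one cell, with the never-screened stage-1A -> 1B substitution:
# stage 1A cancers would not be found without screening, so in never-screened
# women they are assigned stage 1B survival (relaxed by fatality_rule_1a)
cell_rho <- function(fatality, band, stage, category,
                     fatality_rule_1a = "substitute_1b") {
  s <- stage
  if (stage == "1A" && category == "not_screened" &&
      fatality_rule_1a == "substitute_1b") s <- "1B"
  rho <- table_cell(fatality, "rho", age_band = band, stage = s)
  if (is.na(rho)) stop("no case fatality for band ", band, ", stage ", s)
  rho
}

#' Excess deaths within 5 years of diagnosis
#'
#' Multiplies each cell of a (possibly counterfactual) count table by the
#' matching case fatality \eqn{\rho} = 1 - 5-year relative survival and sums
#' per age band. Never-screened stage-1A cells use stage 1B fatality under the
#' default rule (\code{"substitute_1b"}); \code{"keep_1a"} is the sensitivity
#' variant.
#'
#' @param counts a [case_count_table] (from [counterfactual_cancers()] or the
#'   observed counts)
#' @param fatality a [fatality_table] on the bands of \code{counts}
#' @param fatality_rule_1a \code{"substitute_1b"} or \code{"keep_1a"}
#' @return named vector of deaths per age band
#' @export
excess_deaths <- function(counts, fatality,
                          fatality_rule_1a = c("substitute_1b", "keep_1a")) {
  fatality_rule_1a <- match.arg(fatality_rule_1a)
  counts <- case_count_table(counts)
  if (any(counts$stage == "unknown"))
    stop("reallocate unknown-stage cases before computing deaths")
  rho <- mapply(cell_rho, band = counts$age_band, stage = counts$stage,
                category = counts$category,
                MoreArgs = list(fatality = fatality,
                                fatality_rule_1a = fatality_rule_1a))
  d <- tapply(counts$count * rho, counts$age_band, sum)
  setNames(as.numeric(d), names(d))
}

#' Indirect (stage-combined) relative risk with delta-method CI
#'
#' Combines stage-specific counts and odds ratios into the marginal relative
#' risk of one screening category versus never screened, within one age band.
#' Incidence: \deqn{RR = \sum_s N_{s} \; / \; \sum_s N_{s}/\mathrm{OR}_{s}.}
#' Mortality weights the numerator cells by the category's observed-stage
#' fatality and the denominator cells by never-screened fatality with the
#' stage-1A-to-1B substitution. The variance of \eqn{\log RR} is the
#' delta-method combination \eqn{\sum_s w_s^2 \mathrm{se}_s^2} with
#' \eqn{w_s} the stage's share of the denominator sum, giving
#' \eqn{CI = \exp(\log RR \pm 1.96 \sqrt{var})}.
#'
#' @param counts a reallocated [case_count_table]
#' @param ors an [or_table]
#' @param fatality a [fatality_table] on the band (see [collapse_fatality()]);
#'   required for \code{endpoint = "mortality"}
#' @param endpoint \code{"incidence"} or \code{"mortality"}
#' @param category the screening category being compared with never screened
#' @param band the odds-ratio age band
#' @param fatality_rule_1a see [excess_deaths()]
#' @return list of class \code{rr_ci}: \code{rr}, \code{lo}, \code{hi},
#'   \code{var_log}, plus the numerator/denominator sums
#' @export
indirect_rr <- function(counts, ors, fatality = NULL,
                        endpoint = c("incidence", "mortality"),
                        category, band,
                        fatality_rule_1a = c("substitute_1b", "keep_1a")) {
  endpoint <- match.arg(endpoint)
  fatality_rule_1a <- match.arg(fatality_rule_1a)
  if (category == "not_screened")
    return(structure(list(rr = 1, lo = 1, hi = 1, var_log = 0),
                     class = "rr_ci"))
  i <- counts$age_band == band & counts$stage != "unknown" &
    !is.na(counts$category) & counts$category == category
  if (!any(i)) stop("no cases for category ", category, " in band ", band)
  stages <- counts$stage[i]
  n <- counts$count[i]
  or <- vapply(stages, function(s)
    table_cell(ors, "or", age_band = band, stage = s, category = category),
    numeric(1))
  se <- vapply(stages, function(s)
    table_cell(ors, "se_log", age_band = band, stage = s, category = category),
    numeric(1))
  if (anyNA(or)) stop("missing odds ratio in band ", band)
  if (endpoint == "mortality") {
    if (is.null(fatality)) stop("mortality endpoint needs a fatality table")
    rho_num <- vapply(stages, function(s)
      cell_rho(fatality, band, s, category, "keep_1a"), numeric(1))
    rho_den <- vapply(stages, function(s)
      cell_rho(fatality, band, s, "not_screened", fatality_rule_1a),
      numeric(1))
  } else {
    rho_num <- rho_den <- rep(1, length(stages))
  }
  num <- n * rho_num
  den <- (n / or) * rho_den
  rr <- sum(num) / sum(den)
  w <- den / sum(den)
  var_log <- sum(w^2 * se^2)
  structure(list(rr = rr,
                 lo = rr * exp(-1.96 * sqrt(var_log)),
                 hi = rr * exp(1.96 * sqrt(var_log)),
                 var_log = var_log, numerator = sum(num),
                 denominator = sum(den)),
            class = "rr_ci")
}

#' @export
print.rr_ci <- function(x, ...) {
  cat(sprintf("RR %.3f (95%% CI %.3f-%.3f)\n", x$rr, x$lo, x$hi))
  invisible(x)
}

#' Deaths-prevented accounting across age bands
#'
#' Converts per-band relative 5-year mortality (no-screening and universal
#' regular screening, each vs current screening) into absolute annual deaths:
#' the estimated deaths in each age-at-death band are RR x observed deaths;
#' deaths observed outside the covered bands (under 25 or over the last band
#' at diagnosis) are not preventable by screening and are carried unchanged
#' into every scenario. Reports additional deaths absent screening, further
#' preventable deaths under universal regular screening, and the prevented /
#' preventable fractions, with intervals from the variance-weighted sum of
#' the band estimates.
#'
#' When \code{projection} carries \code{est_no_screening} /
#' \code{est_all_regular} columns (band estimates computed at higher precision
#' than the rounded RRs, as in a published table), those are used for the
#' point accounting and the RRs supply the variances only.
#'
#' @param projection data.frame with \code{diag_band}, \code{death_band},
#'   \code{rr_no_screening(_lo,_hi)}, \code{rr_all_regular(_lo,_hi)} and
#'   optionally the \code{est_*} columns
#' @param observed an [observed_deaths] table covering the death bands plus
#'   \code{all_ages}
#' @return list of class \code{deaths_report}; see the fields printed by its
#'   \code{print} method
#' @export
deaths_prevented <- function(projection, observed) {
  observed <- observed_deaths(observed)
  bands <- observed[observed$role == "band", ]
  obs <- bands$deaths[match(projection$death_band, bands$death_band)]
  if (anyNA(obs))
    stop("observed deaths missing for band(s): ",
         paste(projection$death_band[is.na(obs)], collapse = ", "))
  all_obs <- observed$deaths[observed$role == "total"]
  # deaths outside the screening-age bands; a printed covered-bands subtotal
  # (exact where the per-band averages are rounded) takes precedence
  covered <- if (any(observed$role == "covered"))
    observed$deaths[observed$role == "covered"][1] else sum(obs)
  remainder <- all_obs - covered
  est_ns <- if ("est_no_screening" %in% names(projection))
    projection$est_no_screening else projection$rr_no_screening * obs
  est_reg <- if ("est_all_regular" %in% names(projection))
    projection$est_all_regular else projection$rr_all_regular * obs
  var_log_ns <- ((log(projection$rr_no_screening_hi) -
                    log(projection$rr_no_screening_lo)) / (2 * 1.96))^2
  var_log_reg <- ((log(projection$rr_all_regular_hi) -
                     log(projection$rr_all_regular_lo)) / (2 * 1.96))^2
  tot_ns <- sum(est_ns) + remainder
  tot_reg <- sum(est_reg) + remainder
  # delta method: var(sum RR_b x obs_b) = sum (est_b)^2 var(log RR_b)
  var_ns <- sum(est_ns^2 * var_log_ns)
  var_reg <- sum(est_reg^2 * var_log_reg)
  ci <- function(tot, v) {
    sd_log <- sqrt(v) / tot
    c(lo = tot * exp(-1.96 * sd_log), hi = tot * exp(1.96 * sd_log))
  }
  structure(list(
    by_band = data.frame(projection[, c("diag_band", "death_band")],
                         observed = obs, est_no_screening = est_ns,
                         est_all_regular = est_reg),
    remainder = remainder,
    observed_all = all_obs,
    total_no_screening = tot_ns, ci_no_screening = ci(tot_ns, var_ns),
    total_all_regular = tot_reg, ci_all_regular = ci(tot_reg, var_reg),
    additional_deaths = tot_ns - all_obs,
    further_preventable = all_obs - tot_reg,
    prevented_fraction_current = 1 - all_obs / tot_ns,
    preventable_fraction_regular = 1 - tot_reg / tot_ns),
    class = "deaths_report")
}

#' @export
print.deaths_report <- function(x, ...) {
  cat("Annual cervical cancer deaths\n")
  cat(sprintf("  observed (all ages):          %8.1f\n", x$observed_all))
  cat(sprintf("  absent screening:             %8.1f (%.0f-%.0f)\n",
              x$total_no_screening, x$ci_no_screening["lo"],
              x$ci_no_screening["hi"]))
  cat(sprintf("  everyone regularly screened:  %8.1f (%.0f-%.0f)\n",
              x$total_all_regular, x$ci_all_regular["lo"],
              x$ci_all_regular["hi"]))
  cat(sprintf("  additional absent screening:  %8.1f\n", x$additional_deaths))
  cat(sprintf("  further preventable:          %8.1f\n", x$further_preventable))
  cat(sprintf("  prevented by current screening: %5.1f%%\n",
              100 * x$prevented_fraction_current))
  cat(sprintf("  preventable with regular screening: %.1f%%\n",
              100 * x$preventable_fraction_regular))
  invisible(x)
}

#' Parametric bootstrap check of the delta-method interval
#'
#' Resamples each stage-specific log odds ratio from its normal approximation,
#' recomputes the indirect relative risk, and returns percentile interval
#' endpoints -- an independent check on the delta-method CI.
#'
#' @inheritParams indirect_rr
#' @param n_rep bootstrap replicates
#' @param seed RNG seed
#' @return vector \code{c(lo, hi)} of 2.5/97.5 percentiles of the resampled RR
#' @export
bootstrap_rr_ci <- function(counts, ors, fatality = NULL,
                            endpoint = c("incidence", "mortality"),
                            category, band,
                            fatality_rule_1a = c("substitute_1b", "keep_1a"),
                            n_rep = 10000, seed = 1) {
  endpoint <- match.arg(endpoint)
  fatality_rule_1a <- match.arg(fatality_rule_1a)
  set.seed(seed)
  i <- counts$age_band == band & counts$stage != "unknown" &
    !is.na(counts$category) & counts$category == category
  stages <- counts$stage[i]
  n <- counts$count[i]
  or <- vapply(stages, function(s)
    table_cell(ors, "or", age_band = band, stage = s, category = category),
    numeric(1))
  se <- vapply(stages, function(s)
    table_cell(ors, "se_log", age_band = band, stage = s, category = category),
    numeric(1))
  if (endpoint == "mortality") {
    rho_num <- vapply(stages, function(s)
      cell_rho(fatality, band, s, category, "keep_1a"), numeric(1))
    rho_den <- vapply(stages, function(s)
      cell_rho(fatality, band, s, "not_screened", fatality_rule_1a), numeric(1))
  } else rho_num <- rho_den <- rep(1, length(stages))
  draws <- matrix(stats::rnorm(n_rep * length(or), log(or), se),
                  ncol = length(or), byrow = TRUE)
  rr <- apply(draws, 1, function(lor)
    sum(n * rho_num) / sum(n / exp(lor) * rho_den))
  stats::quantile(rr, c(0.025, 0.975), names = FALSE)
}
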