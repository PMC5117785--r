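#' Scenario relative mortality (or incidence) vs current screening
#'
#' Ratio of the deaths (or cancers) expected under a counterfactual scenario
#' to those under current screening, within one odds-ratio age band. The
#' variance of the log ratio is a delta-method combination over every odds
#' ratio entering the scenario, with numerically differentiated weights.
#'
#' @inheritParams indirect_rr
#' @param scenario \code{"no_screening"} or \code{"all_regular"}
#' @return an \code{rr_ci} list
#' @export
scenario_rr <- function(counts, ors, fatality = NULL,
                        scenario = c("no_screening", "all_regular"),
                        endpoint = c("mortality", "incidence"), band,
                        fatality_rule_1a = c("substitute_1b", "keep_1a")) {
  scenario <- match.arg(scenario)
  endpoint <- match.arg(endpoint)
  fatality_rule_1a <- match.arg(fatality_rule_1a)
  sub_counts <- case_count_table(counts[counts$age_band == band, ])
  total <- function(or_tab, what) {
    cf <- if (what == "current") sub_counts
          else counterfactual_cancers(sub_counts, or_tab, what)
    if (endpoint == "mortality")
      sum(excess_deaths(cf, fatality, fatality_rule_1a))
    else sum(cf$count)
  }
  cur <- total(ors, "current")
  est <- total(ors, scenario)
  # delta method via numeric gradient of log(estimate) in each log OR
  free <- which(ors$age_band == band & ors$category != "not_screened" &
                  ors$se_log > 0)
  eps <- 1e-5
  grad <- vapply(free, function(k) {
    pert <- ors
    pert$or[k] <- pert$or[k] * exp(eps)
    (log(total(pert, scenario)) - log(est)) / eps
  }, numeric(1))
  var_log <- sum(grad^2 * ors$se_log[free]^2)
  rr <- est / cur
  structure(list(rr = rr, lo = rr * exp(-1.96 * sqrt(var_log)),
                 hi = rr * exp(1.96 * sqrt(var_log)), var_log = var_log),
            class = "rr_ci")
}

pipeline_defaults <- function() {
  list(mode = "fixture", fixture = "england_audit", n_sets = 1000, seed = 1,
       window_years = 15, missing_stage_mode = "proportional_1b_2_3",
       fatality_rule_1a = "substitute_1b", iterate_raking = FALSE,
       min_age = 25.5, output = "screenimpact-run")
}

#' Aggregate a classified cohort into a case-count table
#'
#' Counts cases per (odds-ratio band, stage, category); unknown-stage cases
#' form \code{stage = "unknown"} rows with no category, ready for
#' [reallocate_missing()].
#'
#' @inheritParams fit_clr
#' @return a [case_count_table]
#' @export
cohort_case_counts <- function(women, categories) {
  cases <- women[women$is_case, ]
  band <- age_band_of(age_at(cases$reference_date, cases$birth_date),
                      or_bands())
  cat <- categories$category[match(cases$woman_id, categories$woman_id)]
  stage <- ifelse(is.na(cases$stage), "unknown", cases$stage)
  cat[stage == "unknown"] <- NA
  agg <- stats::aggregate(list(count = rep(1, nrow(cases))),
                          by = list(age_band = band, stage = stage,
                                    category = ifelse(is.na(cat), "", cat)),
                          FUN = sum)
  agg$category[agg$category == ""] <- NA
  case_count_table(agg[order(agg$age_band, agg$stage), ])
}

#' Run the full estimation pipeline
#'
#' Orchestrates simulate -> classify -> fit -> impute -> estimate from a
#' config (a list or a YAML file). \code{mode = "fixture"} starts from the
#' packaged aggregate tables (no individual data); \code{mode = "synthetic"}
#' simulates a cohort, classifies the smear histories, fits the
#' stage-specific odds ratios and proceeds from those. Every intermediate
#' table is written to the output directory together with a summary and a
#' manifest (seed, config hash, package version); the same config and seed
#' reproduce the outputs byte for byte.
#'
#' Config keys (with defaults): \code{mode} ("fixture"), \code{fixture}
#' ("england_audit"), \code{n_sets} (1000), \code{seed} (1),
#' \code{window_years} (15; sensitivity 12 or 8), \code{missing_stage_mode}
#' ("proportional_1b_2_3"), \code{fatality_rule_1a} ("substitute_1b"),
#' \code{iterate_raking} (FALSE), \code{min_age} (25.5; 24.5 includes the
#' first-screen prevalence peak), \code{output} (directory).
#'
#' @param config a named list, or the path of a YAML file of the keys above
#' @param output overrides the config's output directory
#' @return invisibly, a list with the tables computed (\code{counts},
#'   \code{ors}, \code{fatality}, \code{rr_table}, \code{deaths_report},
#'   \code{manifest})
#' @export
run_pipeline <- function(config = list(), output = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!is.null(output)) cfg$output <- output
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  fx <- load_fixture_tables(cfg$fixture)
  if (cfg$mode == "synthetic") {
    sc <- sim_config(n_sets = cfg$n_sets, seed = cfg$seed,
                     window_years = cfg$window_years)
    cohort <- simulate_cohort(sc)
    write_cohort(cohort, file.path(cfg$output, "cohort"))
    categories <- classify_cohort(cohort$women, cohort$smears,
                                  cfg$window_years)
    utils::write.csv(categories, file.path(cfg$output, "categories.csv"),
                     row.names = FALSE)
    counts <- cohort_case_counts(cohort$women, categories)
    ors <- stage_specific_ors(cohort$women, categories)
  } else {
    counts <- fx$counts
    ors <- fx$ors
  }
  write_table(counts, file.path(cfg$output, "counts_raw.csv"))
  write_table(ors, file.path(cfg$output, "ors.csv"))
  counts <- reallocate_missing(counts, cfg$missing_stage_mode)
  write_table(counts, file.path(cfg$output, "counts_imputed.csv"))
  fatality <- collapse_fatality(fx$fatality)
  write_table(fatality, file.path(cfg$output, "fatality.csv"))
  # indirect RRs per band x category x endpoint
  rows <- list()
  for (band in unique(counts$age_band)) {
    for (catg in setdiff(intersect(category_levels(band),
                                   unique(ors$category[ors$age_band == band])),
                         "not_screened")) {
      for (ep in c("incidence", "mortality")) {
        r <- tryCatch(
          indirect_rr(counts, ors, fatality, ep, catg, band,
                      cfg$fatality_rule_1a),
          error = function(e) NULL)
        if (is.null(r)) next
        rows[[paste(band, catg, ep)]] <- data.frame(
          age_band = band, category = catg, endpoint = ep, rr = r$rr,
          lo = r$lo, hi = r$hi, stringsAsFactors = FALSE)
      }
    }
  }
  rr_table <- do.call(rbind, rows)
  rownames(rr_table) <- NULL
  utils::write.csv(rr_table, file.path(cfg$output, "rr_table.csv"),
                   row.names = FALSE)
  # deaths projection at odds-ratio band granularity
  band_death <- c("25.5-34" = "25-39", "35-64" = "40-69", "65-79" = "70-84")
  obs <- fx$deaths
  obs_agg <- data.frame(
    death_band = c("25-39", "40-69", "70-84", "all_ages"),
    deaths = c(obs$deaths[obs$death_band == "25-39"],
               sum(obs$deaths[obs$death_band %in% c("40-54", "55-69")]),
               obs$deaths[obs$death_band == "70-84"],
               obs$deaths[obs$death_band == "all_ages"]))
  proj <- do.call(rbind, lapply(unique(counts$age_band), function(band) {
    ns <- scenario_rr(counts, ors, fatality, "no_screening", "mortality",
                      band, cfg$fatality_rule_1a)
    reg <- scenario_rr(counts, ors, fatality, "all_regular", "mortality",
                       band, cfg$fatality_rule_1a)
    data.frame(diag_band = band, death_band = band_death[[band]],
               rr_no_screening = ns$rr, rr_no_screening_lo = ns$lo,
               rr_no_screening_hi = ns$hi, rr_all_regular = reg$rr,
               rr_all_regular_lo = reg$lo, rr_all_regular_hi = reg$hi,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(proj, file.path(cfg$output, "projection.csv"),
                   row.names = FALSE)
  report <- deaths_prevented(proj, observed_deaths(obs_agg))
  utils::write.csv(report$by_band, file.path(cfg$output, "deaths_report.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(cfg$output, "config.yaml")
  yaml::write_yaml(cfg[order(names(cfg))], cfg_path)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(
                     utils::packageVersion("screenimpact")))
  yaml::write_yaml(manifest, file.path(cfg$output, "manifest.yaml"))
  summary_path <- file.path(cfg$output, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  cat("screenimpact pipeline (", cfg$mode, " mode, seed ", cfg$seed, ")\n\n",
      sep = "")
  print(report)
  sink()
  close(con)
  invisible(list(counts = counts, ors = ors, fatality = fatality,
                 rr_table = rr_table, projection = proj,
                 deaths_report = report, manifest = manifest, config = cfg))
}
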