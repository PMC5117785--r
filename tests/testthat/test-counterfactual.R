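test_that("counterfactual cancers divide by the odds ratio cell-wise", {
  toy <- toy_instance()
  one <- case_count_table(data.frame(age_band = "35-64", stage = "1B",
                                     category = "regular", count = 100))
  or_half <- or_table(data.frame(age_band = "35-64", stage = "1B",
                                 category = "regular", or = 0.5, lo = 0.4,
                                 hi = 0.6, se_log = 0.1))
  out <- counterfactual_cancers(one, or_half, "no_screening")
  expect_equal(out$count, 200)
  expect_equal(out$category, "not_screened")
  # all ORs 1: the projection conserves the counts
  or_null <- transform(fx$ors, or = 1, lo = 1, hi = 1)
  ns <- counterfactual_cancers(reallocate_missing(fx$counts),
                               or_table(or_null), "no_screening")
  expect_equal(sum(ns$count), 11619, tolerance = 1e-9)
  # current is the identity; missing OR cells are an error
  expect_equal(counterfactual_cancers(toy$counts, toy$ors, "current"),
               toy$counts)
  expect_error(counterfactual_cancers(one, toy$ors["1", , drop = FALSE],
                                      "no_screening"), "missing odds ratio")
})

test_that("the full audit projection yields 2-3 times as many cancers absent screening", {
  cts <- reallocate_missing(fx$counts)
  ns <- counterfactual_cancers(cts, fx$ors, "no_screening")
  ratio <- sum(ns$count) / sum(cts$count)
  # regression value; the coarse printed bands pull it slightly under the
  # finer-strata published figure of about 2.5
  expect_equal(ratio, 2.441018, tolerance = 1e-5)
  reg <- counterfactual_cancers(cts, fx$ors, "all_regular")
  expect_equal(sum(reg$count) / sum(cts$count), 0.6361033, tolerance = 1e-5)
})

test_that("excess deaths apply case fatality with the stage-1A substitution", {
  toy <- toy_instance()
  cells <- case_count_table(data.frame(age_band = "35-64", stage = "2",
                                       category = "regular", count = 100))
  expect_equal(unname(excess_deaths(cells, toy$fatality)), 50)
  # never-screened stage 1A takes stage 1B fatality by default
  cell_1a <- case_count_table(data.frame(age_band = "35-64", stage = "1A",
                                         category = "not_screened",
                                         count = 100))
  expect_equal(unname(excess_deaths(cell_1a, toy$fatality)), 8.8)
  kept <- unname(excess_deaths(cell_1a, toy$fatality, "keep_1a"))
  expect_equal(kept, 1.4)
  expect_lt(kept, 8.8)
  # screened stage 1A keeps its own fatality under the default rule
  cell_1a_reg <- transform(cell_1a, category = "regular")
  expect_equal(unname(excess_deaths(case_count_table(cell_1a_reg),
                                    toy$fatality)), 1.4)
})

test_that("indirect RR equals direct arithmetic on a two-stage instance", {
  toy <- toy_instance()
  rr <- indirect_rr(toy$counts, toy$ors, endpoint = "incidence",
                    category = "regular", band = "35-64")
  # spreadsheet-style oracle
  num <- 80 + 10
  den <- 80 / 0.4 + 10 / 0.1
  expect_equal(rr$rr, num / den, tolerance = 1e-12)
  w <- c(80 / 0.4, 10 / 0.1) / den
  se <- c(log(0.53 / 0.3), log(0.2 / 0.05)) / 3.92
  expect_equal(rr$var_log, sum(w^2 * se^2), tolerance = 1e-12)
  expect_equal(rr$lo, rr$rr * exp(-1.96 * sqrt(rr$var_log)), tolerance = 1e-12)
  # mortality combination, hand-computed
  mrr <- indirect_rr(toy$counts, toy$ors, toy$fatality, "mortality",
                     "regular", "35-64")
  mnum <- 80 * 0.088 + 10 * 0.8
  mden <- (80 / 0.4) * 0.088 + (10 / 0.1) * 0.8
  expect_equal(mrr$rr, mnum / mden, tolerance = 1e-12)
  # referent category: RR 1 by definition
  expect_equal(indirect_rr(toy$counts, toy$ors, endpoint = "incidence",
                           category = "not_screened", band = "35-64")$rr, 1)
})

test_that("combined RRs sit inside the stage-specific OR range and order by endpoint", {
  cts <- reallocate_missing(fx$counts)
  fat <- collapse_fatality(fx$fatality)
  for (band in c("35-64", "65-79")) {
    for (catg in c("regular", "irregular")) {
      ors_cell <- fx$ors$or[fx$ors$age_band == band &
                              fx$ors$category == catg]
      inc <- indirect_rr(cts, fx$ors, endpoint = "incidence",
                         category = catg, band = band)
      expect_gte(inc$rr, min(ors_cell))
      expect_lte(inc$rr, max(ors_cell))
      # ORs fall and fatality rises with stage: mortality benefit is larger
      mort <- indirect_rr(cts, fx$ors, fat, "mortality", catg, band)
      expect_lte(mort$rr, inc$rr)
    }
  }
})

test_that("deaths-prevented arithmetic on a single band", {
  proj <- data.frame(diag_band = "35-49", death_band = "40-54",
                     rr_no_screening = 2, rr_no_screening_lo = 1.5,
                     rr_no_screening_hi = 2.67, rr_all_regular = 0.5,
                     rr_all_regular_lo = 0.4, rr_all_regular_hi = 0.63)
  obs <- data.frame(death_band = c("40-54", "all_ages"), deaths = c(100, 100))
  rep <- deaths_prevented(proj, obs)
  expect_equal(rep$additional_deaths, 100)
  expect_equal(rep$further_preventable, 50)
  expect_equal(rep$prevented_fraction_current, 0.5)
  expect_error(deaths_prevented(transform(proj, death_band = "55-69"), obs),
               "missing")
})

test_that("scenario mortality ratios have the expected direction and magnitude", {
  cts <- reallocate_missing(fx$counts)
  fat <- collapse_fatality(fx$fatality)
  ns <- scenario_rr(cts, fx$ors, fat, "no_screening", "mortality", "35-64")
  reg <- scenario_rr(cts, fx$ors, fat, "all_regular", "mortality", "35-64")
  expect_gt(ns$rr, 3)        # several-fold higher mortality absent screening
  expect_lt(reg$rr, 0.6)     # under half with universal regular screening
  expect_true(ns$lo < ns$rr && ns$rr < ns$hi)
})
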