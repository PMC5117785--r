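test_that("conditional log-likelihood at beta = 0 is -sum log set size", {
  sets <- make_sets(list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(conditional_loglik(0, sets$X, sets$case, sets$set),
               -4 * log(3))
})

test_that("conditional log-likelihood matches an independent direct evaluation", {
  set.seed(5)
  for (i in 1:20) {
    n_sets <- sample(2:4, 1)
    xs <- lapply(seq_len(n_sets), function(k) rbinom(sample(2:3, 1), 1, 0.5))
    s <- make_sets(xs)
    beta <- rnorm(1)
    expect_equal(conditional_loglik(beta, s$X, s$case, s$set),
                 oracle_clr_loglik(beta, s$X, s$case, s$set),
                 tolerance = 1e-12)
  }
})

test_that("a symmetric pair of sets yields an odds ratio of exactly 1", {
  # case exposed with controls {exposed, unexposed}; mirror-image set
  s <- make_sets(list(c(1, 1, 0), c(0, 1, 0)))
  fit <- fit_clr_matrix(s$X, s$case, s$set)
  expect_true(fit$converged)
  expect_equal(unname(exp(fit$beta)), 1, tolerance = 1e-8)
})

test_that("Newton estimate agrees with a grid-search maximiser to 1e-3", {
  set.seed(8)
  xs <- lapply(1:10, function(k) rbinom(3, 1, 0.4))
  xs[[1]] <- c(1, 0, 0)   # guarantee an informative set
  s <- make_sets(xs)
  fit <- fit_clr_matrix(s$X, s$case, s$set)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    oracle_clr_loglik(b, s$X, s$case, s$set), numeric(1))
  expect_lt(abs(unname(fit$beta) - grid[which.max(ll)]), 1e-3)
})

test_that("the gradient vanishes at the fitted coefficients", {
  co <- simulate_cohort(sim_config(n_sets = 400, seed = 17))
  cl <- classify_cohort(co$women, co$smears)
  fit <- direct_or(co$women, cl, "35-64")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-6)
})

test_that("coefficients and standard errors match survival::clogit", {
  skip_if_not_installed("survival")
  co <- simulate_cohort(sim_config(n_sets = 600, seed = 23))
  cl <- classify_cohort(co$women, co$smears)
  fit <- direct_or(co$women, cl, "35-64")
  w <- co$women
  w$ref_age <- age_at(w$reference_date, w$birth_date)
  sets <- w$set_id[w$is_case & age_band_of(w$ref_age, or_bands()) == "35-64"]
  sub <- w[w$set_id %in% sets, ]
  sub$cat <- factor(cl$category[match(sub$woman_id, cl$woman_id)],
                    levels = category_levels())
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(sub)), sub$is_case) ~ cat +
      survival::strata(set_id),
    data = sub, method = "exact")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("the fitter recovers a strong protective generator effect", {
  # stage 3+ regular screening OR 0.05 at ages 35-64, as configured
  co <- simulate_cohort(sim_config(n_sets = 2500, seed = 29))
  cl <- classify_cohort(co$women, co$smears)
  ors <- stage_specific_ors(co$women, cl)
  cell <- subset(ors, age_band == "35-64" & stage == "3plus" &
                   category == "regular")
  expect_lt(abs(log(cell$or) - log(0.05)), 3 * cell$se_log)
})

test_that("the trend model uses the ordinal score and detects the gradient", {
  co <- simulate_cohort(sim_config(n_sets = 800, seed = 41))
  cl <- classify_cohort(co$women, co$smears)
  w <- co$women
  w$ref_age <- age_at(w$reference_date, w$birth_date)
  sets <- w$set_id[w$is_case & age_band_of(w$ref_age, or_bands()) == "35-64"]
  fit <- fit_clr(w[w$set_id %in% sets, ], cl, model = "trend")
  expect_true(fit$converged)
  expect_lt(exp(fit$beta[["trend"]]), 1)   # protective per regularity step
})

test_that("complete separation is flagged, structural errors are raised", {
  # case always exposed, controls never: likelihood maximised at +infinity
  s <- make_sets(list(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  fit <- fit_clr_matrix(s$X, s$case, s$set)
  expect_false(fit$converged)
  expect_equal(unname(fit$separation_direction), 1)
  # all sets non-informative
  s2 <- make_sets(list(c(1, 1, 1), c(0, 0, 0)))
  expect_error(fit_clr_matrix(s2$X, s2$case, s2$set), "informative")
  # a set without a case
  expect_error(conditional_loglik(0, matrix(c(1, 0), 2), c(FALSE, FALSE),
                                  c("a", "a")), "exactly one case")
})
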