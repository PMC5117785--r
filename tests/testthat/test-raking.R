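make_grid <- function(survival, bands, stages) {
  data.frame(age_band = rep(bands, times = length(stages)),
             stage = rep(stages, each = length(bands)),
             survival = survival)
}

equal_weights <- function(grid) {
  data.frame(grid[, c("age_band", "stage")], weight = 1)
}

# independent bisection oracle for sum(w s^h)/sum(w) = target
bisect_h <- function(s, w, target) {
  f <- function(h) sum(w * s^h) / sum(w) - target
  lo <- 1e-3; hi <- 1e3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("hazard-ratio exponentiation behaves as s^h", {
  expect_equal(apply_hazard_ratio(0.7, 1), 0.7)
  expect_equal(apply_hazard_ratio(0.81, 2), 0.6561)
  s <- 0.37
  expect_equal(apply_hazard_ratio(apply_hazard_ratio(s, 2.7), 1 / 2.7), s,
               tolerance = 1e-12)
  expect_error(apply_hazard_ratio(0.5, -1), "positive")
  expect_error(apply_hazard_ratio(0, 0.5), "cannot")
})

test_that("a grid already matching its marginals is a fixed point", {
  grid <- make_grid(c(0.9, 0.8, 0.6, 0.5), c("a1", "a2"), c("s1", "s2"))
  w <- equal_weights(grid)
  sm <- c(s1 = 0.85, s2 = 0.55)
  am <- c(a1 = 0.75, a2 = 0.65)
  out <- rake_survival(grid, sm, am, w)
  expect_equal(unname(attr(out, "h_stage")), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(attr(out, "h_age")), c(1, 1), tolerance = 1e-6)
  expect_equal(out$survival, grid$survival, tolerance = 1e-8)
})

test_that("pass 1 hits the stage marginals and matches a bisection oracle", {
  grid <- make_grid(c(0.95, 0.88, 0.62, 0.48), c("a1", "a2"), c("s1", "s2"))
  w <- equal_weights(grid)
  sm <- c(s1 = 0.9, s2 = 0.5)
  # age targets chosen attainable but non-trivial
  out <- rake_survival(grid, sm, c(a1 = 0.78, a2 = 0.60), w)
  h <- attr(out, "h_stage")
  expect_equal(unname(h["s1"]),
               bisect_h(c(0.95, 0.88), c(1, 1), 0.9), tolerance = 1e-7)
  expect_equal(unname(h["s2"]),
               bisect_h(c(0.62, 0.48), c(1, 1), 0.5), tolerance = 1e-7)
  # after pass 2 the age marginals match to 1e-8
  for (a in c("a1", "a2")) {
    m <- mean(out$survival[out$age_band == a])
    expect_equal(m, c(a1 = 0.78, a2 = 0.60)[[a]], tolerance = 1e-8)
  }
})

test_that("the stage pass preserves the within-stage ordering of survival", {
  # one common power per stage is monotone; the later per-age-band powers
  # are a different transformation per cell and need not preserve it
  set.seed(2)
  grid <- make_grid(runif(12, 0.3, 0.95), paste0("a", 1:4), paste0("s", 1:3))
  w <- equal_weights(grid)
  sm <- setNames(runif(3, 0.5, 0.8), paste0("s", 1:3))
  out <- rake_survival(grid, sm, setNames(numeric(0), character(0)), w)
  for (s in paste0("s", 1:3)) {
    i <- grid$stage == s
    expect_equal(order(grid$survival[i]), order(out$survival[i]))
  }
})

test_that("iterated raking shrinks the marginal discrepancies monotonically", {
  # jointly attainable targets: marginals of a reference grid, raked from a
  # power-perturbed start
  set.seed(4)
  truth <- make_grid(runif(12, 0.4, 0.95), paste0("a", 1:4), paste0("s", 1:3))
  w <- equal_weights(truth)
  sm <- sapply(split(truth, truth$stage), function(d) mean(d$survival))
  am <- sapply(split(truth, truth$age_band), function(d) mean(d$survival))
  start <- truth
  start$survival <- truth$survival^runif(12, 0.7, 1.4)
  iterated <- rake_survival(start, sm, am, w, iterate = TRUE,
                            max_cycles = 200)
  trace <- attr(iterated, "discrepancy_trace")
  expect_true(all(diff(trace) <= 1e-12))
  expect_lt(trace[length(trace)], trace[1])
  # and it beats a single two-pass cycle
  two_pass <- rake_survival(start, sm, am, w)
  expect_lte(trace[length(trace)], attr(two_pass, "discrepancy_trace")[1])
})

test_that("raking the packaged fatality grid to its own marginals returns it", {
  surv <- fx$fatality
  surv$survival <- 1 - surv$rho
  staged <- fx$counts[fx$counts$stage != "unknown", ]
  staged$age_band[staged$age_band == "65-79"] <- "65-69"  # coarse-to-fine proxy
  wt <- aggregate(list(weight = staged$count),
                  by = list(stage = staged$stage), FUN = sum)
  w <- merge(surv[, c("age_band", "stage")], wt, by = "stage")
  g <- merge(surv, w, by = c("age_band", "stage"))
  sm <- sapply(split(g, g$stage), function(d)
    sum(d$weight * d$survival) / sum(d$weight))
  am <- sapply(split(g, g$age_band), function(d)
    sum(d$weight * d$survival) / sum(d$weight))
  out <- rake_survival(surv[, c("age_band", "stage", "survival")], sm, am, w)
  m <- merge(out, fx$fatality, by = c("age_band", "stage"))
  expect_lt(max(abs(m$rho.x - m$rho.y)), 0.005)   # within 0.5 points
})

test_that("unattainable marginals are reported with the offending cell", {
  grid <- make_grid(c(0.9, 0.8), "a1", c("s1", "s2"))
  w <- equal_weights(grid)
  expect_error(rake_survival(grid, c(s1 = 1.5, s2 = 0.5), c(a1 = 0.6), w),
               "unattainable.*s1")
})
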