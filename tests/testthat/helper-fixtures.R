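# shared fixture objects and small builders used across the suite

fx <- load_fixture_tables()

# a window spanning [a, a + len] in decimal age
win <- function(a, len) list(start = a, end = a + len, rule = "lookback")

# matched sets in the layout fit_clr_matrix() expects: one exposure indicator
# x per member, first member of each set is the case
make_sets <- function(x_by_set, case_first = TRUE) {
  set <- rep(seq_along(x_by_set), lengths(x_by_set))
  x <- unlist(x_by_set)
  case <- unlist(lapply(x_by_set, function(v) seq_along(v) == 1))
  list(X = matrix(x, ncol = 1, dimnames = list(NULL, "exposed")),
       case = case, set = paste0("S", set))
}

# independent direct evaluation of the conditional log-likelihood (oracle):
# plain loops, no shared code with the implementation
oracle_clr_loglik <- function(beta, X, case, set) {
  ll <- 0
  for (s in unique(set)) {
    r <- which(set == s)
    num <- exp(sum(X[r[case[r]], ] * beta))
    den <- 0
    for (m in r) den <- den + exp(sum(X[m, ] * beta))
    ll <- ll + log(num / den)
  }
  ll
}

# tiny two-stage aggregate instance used by the counterfactual tests
toy_instance <- function() {
  counts <- case_count_table(data.frame(
    age_band = "35-64",
    stage = rep(c("1B", "3plus"), each = 2),
    category = rep(c("not_screened", "regular"), 2),
    count = c(50, 80, 60, 10)))
  ors <- or_table(data.frame(
    age_band = "35-64", stage = rep(c("1B", "3plus"), each = 2),
    category = rep(c("not_screened", "regular"), 2),
    or = c(1, 0.4, 1, 0.1), lo = c(1, 0.3, 1, 0.05),
    hi = c(1, 0.53, 1, 0.2),
    se_log = c(0, log(0.53 / 0.3) / 3.92, 0, log(0.2 / 0.05) / 3.92)))
  fatality <- fatality_table(data.frame(
    age_band = "35-64", stage = c("1A", "1B", "2", "3plus"),
    rho = c(0.014, 0.088, 0.5, 0.8)))
  list(counts = counts, ors = ors, fatality = fatality)
}
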