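#' Apply a hazard ratio to a 5-year relative survival
#'
#' Under proportional hazards on the cumulative (excess) hazard, a hazard
#' ratio \eqn{h} maps survival \eqn{s} to \eqn{s^h}.
#'
#' @param s survival in (0, 1]
#' @param h positive hazard ratio
#' @return the adjusted survival \eqn{s^h}
#' @export
apply_hazard_ratio <- function(s, h) {
  if (any(h <= 0)) stop("hazard ratio must be positive")
  if (any(s < 0 | s > 1)) stop("survival must lie in [0, 1]")
  if (any(s == 0 & h < 1)) stop("survival 0 cannot be raised by h < 1")
  s^h
}

# solve sum(w * s^h) = target for h; the marginal is strictly decreasing in h
solve_hazard_ratio <- function(s, w, target, label) {
  w <- w / sum(w)
  f <- function(h) sum(w * s^h) - target
  lo <- 1e-3; hi <- 1e3
  if (f(lo) < 0 || f(hi) > 0)
    stop("marginal ", format(target), " unattainable for ", label)
  h <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (k in 1:5) {                     # Newton polish to the 1e-10 tolerance
    fh <- f(h)
    if (abs(fh) < 1e-13) break
    d <- sum(w * s^h * log(s))
    if (d == 0) break
    h <- h - fh / d
  }
  h
}

#' Rake an age x stage survival grid to external marginals
#'
#' Two-pass renormalisation of a joint age-within-stage survival surface (the
#' joint age/stage dependence, e.g. from SEER) to external marginal anchors:
#' pass 1 finds one hazard ratio per stage so the case-weighted marginal
#' survival of each stage matches its target (e.g. the Anglia stage
#' marginals); pass 2 finds one hazard ratio per age band so the age marginals
#' match their targets (e.g. England's age-specific survival). Pass 2 perturbs
#' the pass-1 stage marginals; \code{iterate = TRUE} alternates the two passes
#' to joint convergence instead of stopping after one cycle.
#'
#' @param grid data.frame \code{age_band}, \code{stage}, \code{survival} in
#'   (0, 1]
#' @param stage_marginals named vector, target marginal survival per stage
#' @param age_marginals named vector, target marginal survival per age band
#' @param weights data.frame \code{age_band}, \code{stage}, \code{weight}
#'   (typically case counts); used for both marginalisations
#' @param iterate alternate stage/age passes until both marginals match
#' @param max_cycles,tol iteration controls for \code{iterate = TRUE}
#' @return a [fatality_table] (\code{rho} = 1 - raked survival, clipped into
#'   [0, 1]) with the raked survival in column \code{survival} and the fitted
#'   hazard ratios as attributes \code{h_stage}, \code{h_age}
#' @export
rake_survival <- function(grid, stage_marginals, age_marginals, weights,
                          iterate = FALSE, max_cycles = 50, tol = 1e-10) {
  g <- grid
  key <- paste(g$age_band, g$stage)
  g$weight <- weights$weight[match(key, paste(weights$age_band,
                                              weights$stage))]
  if (anyNA(g$weight)) stop("weights must cover every grid cell")
  if (any(g$survival <= 0 | g$survival > 1))
    stop("grid survival must lie in (0, 1]")
  h_stage <- setNames(rep(1, length(stage_marginals)), names(stage_marginals))
  h_age <- setNames(rep(1, length(age_marginals)), names(age_marginals))
  cycles <- if (iterate) max_cycles else 1L
  trace <- numeric(0)
  for (cy in seq_len(cycles)) {
    for (s in names(stage_marginals)) {          # pass 1: stage marginals
      i <- g$stage == s
      h <- solve_hazard_ratio(g$survival[i], g$weight[i], stage_marginals[[s]],
                              paste("stage", s))
      g$survival[i] <- g$survival[i]^h
      h_stage[s] <- h_stage[s] * h
    }
    for (a in names(age_marginals)) {            # pass 2: age marginals
      i <- g$age_band == a
      h <- solve_hazard_ratio(g$survival[i], g$weight[i], age_marginals[[a]],
                              paste("age band", a))
      g$survival[i] <- g$survival[i]^h
      h_age[a] <- h_age[a] * h
    }
    trace[cy] <- max(marginal_discrepancy(g, stage_marginals, age_marginals))
    if (iterate && trace[cy] < tol) break
  }
  out <- g[, c("age_band", "stage")]
  out$rho <- pmin(pmax(1 - g$survival, 0), 1)
  out <- fatality_table(out)
  out$survival <- g$survival
  attr(out, "h_stage") <- h_stage
  attr(out, "h_age") <- h_age
  attr(out, "discrepancy_trace") <- trace
  out
}

#' @rdname rake_survival
#' @param g a grid data.frame with \code{survival} and \code{weight}
#' @return \code{marginal_discrepancy}: named vector of absolute differences
#'   between the weighted marginals of \code{g} and the targets
#' @export
marginal_discrepancy <- function(g, stage_marginals, age_marginals) {
  d_s <- vapply(names(stage_marginals), function(s) {
    i <- g$stage == s
    abs(sum(g$weight[i] * g$survival[i]) / sum(g$weight[i]) -
          stage_marginals[[s]])
  }, numeric(1))
  d_a <- vapply(names(age_marginals), function(a) {
    i <- g$age_band == a
    abs(sum(g$weight[i] * g$survival[i]) / sum(g$weight[i]) -
          age_marginals[[a]])
  }, numeric(1))
  c(d_s, d_a)
}
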