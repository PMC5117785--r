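#' Conditional log-likelihood for individually matched sets
#'
#' For matched sets with exactly one case, the conditional likelihood of the
#' logistic model eliminates the set-level nuisance parameters:
#' \deqn{\ell(\beta) = \sum_{sets} \left[ x_{case}'\beta -
#'   \log \sum_{m \in set} \exp(x_m'\beta) \right].}
#' Sets whose members share identical covariates contribute a constant.
#'
#' @param beta coefficient vector (length = columns of \code{X})
#' @param X numeric design matrix, one row per woman
#' @param case logical, TRUE for the set's case
#' @param set set identifier, one per row of \code{X}
#' @return the conditional log-likelihood
#' @export
conditional_loglik <- function(beta, X, case, set) {
  X <- as.matrix(X)
  parts <- clr_parts(X, case, set)
  eta <- drop(X %*% beta)
  lse <- vapply(parts$rows, function(r) {
    e <- eta[r]
    m <- max(e)
    m + log(sum(exp(e - m)))
  }, numeric(1))
  sum(eta[parts$case_row]) - sum(lse)
}

clr_parts <- function(X, case, set) {
  rows <- split(seq_len(nrow(X)), set)
  n_case <- vapply(rows, function(r) sum(case[r]), numeric(1))
  if (any(n_case != 1))
    stop("every matched set must contain exactly one case")
  case_row <- vapply(rows, function(r) r[case[r]], integer(1))
  list(rows = rows, case_row = case_row)
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximises [conditional_loglik()] with analytic gradient and Hessian,
#' step-halving when a step decreases the likelihood, starting from
#' \eqn{\beta = 0}. Convergence: change in log-likelihood below \code{tol_ll}
#' or gradient max-norm below \code{tol_grad}. Complete separation is flagged
#' (\code{converged = FALSE} with the runaway direction) when a coefficient
#' diverges while the gradient stays away from zero.
#'
#' @inheritParams conditional_loglik
#' @param max_iter,tol_ll,tol_grad convergence controls
#' @return list of class \code{clr_fit}: \code{beta}, \code{cov} (inverse
#'   observed information), \code{se}, \code{loglik}, \code{converged},
#'   \code{iterations}, \code{gradient}
#' @export
fit_clr_matrix <- function(X, case, set, max_iter = 50, tol_ll = 1e-10,
                           tol_grad = 1e-8) {
  X <- as.matrix(X)
  parts <- clr_parts(X, case, set)
  # non-informative sets (constant covariates) only shift the likelihood
  info <- vapply(parts$rows, function(r)
    nrow(unique(X[r, , drop = FALSE])) > 1, logical(1))
  if (!any(info)) stop("no informative sets: covariates constant within every set")
  keep <- unlist(parts$rows[info], use.names = FALSE)
  offset_ll <- -sum(log(lengths(parts$rows[!info])))
  X <- X[keep, , drop = FALSE]
  case <- case[keep]
  set <- set[keep]
  parts <- clr_parts(X, case, set)
  p <- ncol(X)
  beta <- rep(0, p)
  ll <- conditional_loglik(beta, X, case, set)
  converged <- FALSE
  it <- 0
  grad <- NULL
  repeat {
    it <- it + 1
    eta <- drop(X %*% beta)
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (i in seq_along(parts$rows)) {
      r <- parts$rows[[i]]
      w <- exp(eta[r] - max(eta[r]))
      w <- w / sum(w)
      xr <- X[r, , drop = FALSE]
      mu <- colSums(w * xr)
      g <- g + X[parts$case_row[i], ] - mu
      H <- H + crossprod(xr, w * xr) - tcrossprod(mu)
    }
    if (max(abs(g)) < tol_grad) { converged <- TRUE; grad <- g; break }
    step <- tryCatch(solve(H, g), error = function(e) g / (max(diag(H)) + 1e-12))
    # step-halving keeps the iterates monotone in log-likelihood
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- conditional_loglik(beta_new, X, case, set)
      if (ll_new >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    dll <- ll_new - ll
    beta <- beta_new
    ll <- ll_new
    grad <- g
    if (abs(dll) < tol_ll && max(abs(g)) < 1e-4) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  # a coefficient running to +/- infinity flattens the gradient numerically,
  # so magnitude alone marks the monotone (separated) likelihood
  separated <- max(abs(beta)) > 15
  if (separated) converged <- FALSE
  cov <- tryCatch({
    eta <- drop(X %*% beta)
    H <- matrix(0, p, p)
    for (i in seq_along(parts$rows)) {
      r <- parts$rows[[i]]
      w <- exp(eta[r] - max(eta[r])); w <- w / sum(w)
      xr <- X[r, , drop = FALSE]
      mu <- colSums(w * xr)
      H <- H + crossprod(xr, w * xr) - tcrossprod(mu)
    }
    solve(H)
  }, error = function(e) matrix(NA_real_, p, p))
  structure(list(beta = beta, cov = cov, se = sqrt(diag(cov)),
                 loglik = ll + offset_ll, converged = converged,
                 iterations = it, gradient = grad,
                 separation_direction = if (separated) sign(beta) else NULL),
            class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("<clr_fit> ", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations, loglik ", format(x$loglik), "\n",
      sep = "")
  est <- data.frame(beta = x$beta, se = x$se, or = exp(x$beta),
                    lo = exp(x$beta - 1.96 * x$se),
                    hi = exp(x$beta + 1.96 * x$se))
  rownames(est) <- names(x$beta) %||% paste0("b", seq_along(x$beta))
  print(est)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit screening-category effects in a classified cohort
#'
#' Builds the design from the women table joined to their categories and fits
#' either the categorical model (one indicator per non-referent category, so
#' \code{exp(beta)} are odds ratios vs \code{not_screened}) or the linear-trend
#' model on the ordinal regularity score.
#'
#' @param women a women data.frame (see [simulate_cohort()]) for the sets to fit
#' @param categories output of [classify_cohort()] for the same women
#' @param model \code{"categorical"} or \code{"trend"}
#' @param levels category levels to use (referent first); defaults to the
#'   levels present
#' @param ... passed to [fit_clr_matrix()]
#' @return a \code{clr_fit}; coefficients carry category (or \code{"trend"}) names
#' @export
fit_clr <- function(women, categories, model = c("categorical", "trend"),
                    levels = NULL, ...) {
  model <- match.arg(model)
  cat <- categories$category[match(women$woman_id, categories$woman_id)]
  if (anyNA(cat)) stop("every woman needs a classified category")
  if (is.null(levels))
    levels <- intersect(c("not_screened", "very_irregular", "irregular",
                          "regular"), unique(cat))
  if (model == "trend") {
    X <- matrix(category_score(cat), ncol = 1,
                dimnames = list(NULL, "trend"))
  } else {
    non_ref <- setdiff(levels, "not_screened")
    X <- vapply(non_ref, function(l) as.numeric(cat == l),
                numeric(length(cat)))
    dimnames(X) <- list(NULL, non_ref)
  }
  fit <- fit_clr_matrix(X, as.logical(women$is_case), women$set_id, ...)
  names(fit$beta) <- colnames(X)
  names(fit$se) <- colnames(X)
  fit
}

#' Stage-specific odds-ratio table from a classified cohort
#'
#' For each (odds-ratio age band, FIGO stage): selects the sets whose case is
#' in that band with that stage (controls retained regardless), fits the
#' categorical model against the never-screened referent, and fills an
#' [or_table] with Wald 95\% intervals \code{exp(beta +/- 1.96 se)}. Cases
#' with unknown stage are left out. Empty strata yield no rows (absent, not
#' zero).
#'
#' @inheritParams fit_clr
#' @return an [or_table]
#' @export
stage_specific_ors <- function(women, categories) {
  women$ref_age <- age_at(women$reference_date, women$birth_date)
  case_rows <- women[women$is_case, ]
  case_band <- age_band_of(case_rows$ref_age, or_bands())
  out <- list()
  for (band in unique(case_band)) {
    for (s in stage_levels()) {
      sets <- case_rows$set_id[case_band == band & !is.na(case_rows$stage) &
                                 case_rows$stage == s]
      if (length(sets) == 0) next
      sub <- women[women$set_id %in% sets, ]
      lv <- category_levels(band)
      fit <- tryCatch(fit_clr(sub, categories, "categorical", levels = lv),
                      error = function(e) NULL)
      if (is.null(fit)) next
      non_ref <- names(fit$beta)
      rows <- data.frame(
        age_band = band, stage = s,
        category = c("not_screened", non_ref),
        or = c(1, exp(fit$beta)),
        lo = c(1, exp(fit$beta - 1.96 * fit$se)),
        hi = c(1, exp(fit$beta + 1.96 * fit$se)),
        se_log = c(0, fit$se), stringsAsFactors = FALSE)
      out[[paste(band, s)]] <- rows
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  or_table(tab)
}

#' Pooled (direct) odds ratios ignoring stage
#'
#' The marginal association between screening category and cancer in one age
#' band, fitted without reference to stage -- the direct counterpart of the
#' indirect stage-combined relative risk.
#'
#' @inheritParams fit_clr
#' @param band an odds-ratio band label from [or_bands()]
#' @return a \code{clr_fit}
#' @export
direct_or <- function(women, categories, band) {
  women$ref_age <- age_at(women$reference_date, women$birth_date)
  case_rows <- women[women$is_case, ]
  sets <- case_rows$set_id[age_band_of(case_rows$ref_age, or_bands()) == band]
  fit_clr(women[women$set_id %in% sets, ], categories, "categorical",
          levels = category_levels(band))
}
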