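# Bayesian RBF kernel regression for developmental curves.
#
# Model: one radial-basis function is centred at every training month, so
# the design matrix is the Gram matrix K (K[i, j] = exp(-(x_i - x_j)^2 /
# (2 sigma^2))). Weights w get a zero-mean Gaussian prior with precision
# alpha; observations get Gaussian noise with precision beta. The posterior
# over w is Gaussian with covariance S = (alpha I + beta K'K)^-1 and mean
# m = beta S K' t, and (alpha, beta) are re-estimated by the evidence
# (marginal-likelihood) fixed-point updates
#   gamma = sum_i lambda_i / (alpha + lambda_i),  lambda_i eig of beta K'K
#   alpha <- gamma / m'm,   beta <- (N - gamma) / ||t - K m||^2
# iterated to convergence. Because K is symmetric, one eigendecomposition
# K = V E V' serves every iteration: in the eigenbasis all updates are
# O(N), which is what makes leave-one-out bandwidth selection affordable.

#' RBF Gram matrix
#'
#' `K[i, j] = exp(-(x_i - y_j)^2 / (2 sigma^2))`; with `y = x` (the
#' default) the matrix is symmetric positive semidefinite with unit
#' diagonal.
#'
#' @param x Numeric vector of evaluation points (months).
#' @param sigma Kernel width in months, `> 0`.
#' @param y Optional second set of points (kernel centres); defaults to
#'   `x`.
#' @return A `length(x)` by `length(y)` matrix.
#' @export
#' @examples
#' rbf_gram(c(0, 1, 2), sigma = 1)
rbf_gram <- function(x, sigma, y = x) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  exp(-outer(x, y, `-`)^2 / (2 * sigma^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`. Equals 1
#' for a perfect predictor, 0 for the mean predictor, and is negative for
#' predictors worse than the mean. Undefined (`NA`) when the observations
#' are constant.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 2).
#' @return A single number, or `NA` for constant `observed`.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Default kernel-width search grid
#'
#' Twenty log-spaced widths from 0.5 to 30 months: narrow enough to track
#' genuinely wiggly series, wide enough to flatten to a near-linear trend
#' over a 7-60 month span.
#'
#' @param lo,hi Grid end points in months.
#' @param k Number of grid values.
#' @return Numeric vector of length `k`.
#' @export
default_sigma_grid <- function(lo = 0.5, hi = 30, k = 20) {
  exp(seq(log(lo), log(hi), length.out = k))
}

# Evidence fixed-point iteration in the eigenbasis of K.
#   e  : eigenvalues of K (so K'K has eigenvalues e^2)
#   tb : V' t, the targets rotated into the eigenbasis
# Returns converged (alpha, beta) and the posterior mean in the eigenbasis.
evidence_iterate <- function(e, tb, alpha, beta, max_iter = 1000,
                             tol = 1e-6) {
  n <- length(tb)
  converged <- max_iter == 0
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d <- beta * e * tb / (alpha + beta * e^2)
    mm <- sum(d^2)
    rss <- sum((tb - e * d)^2)
    lam <- beta * e^2
    gam <- sum(lam / (alpha + lam))
    a_new <- if (mm > 0) gam / mm else alpha
    b_new <- if (rss > 1e-12 && n > gam) (n - gam) / rss else beta
    if (!is.finite(a_new) || a_new <= 0) a_new <- alpha
    if (!is.finite(b_new) || b_new <= 0) b_new <- beta
    done <- abs(a_new - alpha) <= tol * alpha &&
      abs(b_new - beta) <= tol * beta
    alpha <- a_new
    beta <- b_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  d <- beta * e * tb / (alpha + beta * e^2)
  list(alpha = alpha, beta = beta, d = d, converged = converged,
       iter = iter)
}

# Posterior mean weights for fixed hyperparameters (the kernel ridge
# solution with penalty alpha / beta), via the same eigenbasis route.
posterior_weights <- function(K, t, alpha, beta) {
  es <- eigen(K, symmetric = TRUE)
  tb <- drop(crossprod(es$vectors, t))
  d <- beta * es$values * tb / (alpha + beta * es$values^2)
  drop(es$vectors %*% d)
}

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fit a Bayesian RBF kernel regression
#'
#' Fits the developmental-curve model at a fixed kernel width `sigma`:
#' Bayesian linear regression in the Gram basis with evidence-approximation
#' updates of the weight precision `alpha` and noise precision `beta` from
#' a seeded random initialization (independent log-normal draws), iterated
#' until both change by less than `tol` (relative) or `max_iter` is
#' reached. Non-convergence yields a warning and `converged = FALSE`, not
#' an error. The predictive mean is evaluated on a dense month grid
#' (`grid_step`, default 0.1 months, matching the sub-month resolution at
#' which onsets and offsets are reported) spanning exactly the observed
#' month range — the model never extrapolates. `R^2` is computed at the
#' training points on the raw scale, and the grid curve is max-normalized
#' for threshold-based feature detection.
#'
#' @param x Numeric vector of months (length at least 3).
#' @param t Numeric vector of observed index values, same length.
#' @param sigma Kernel width in months (from [select_sigma_loocv()] or
#'   fixed by the user).
#' @param seed Integer seed controlling the random initialization of
#'   `(alpha, beta)`.
#' @param alpha0,beta0 Optional fixed initial hyperparameters (bypass the
#'   seeded draw; with `max_iter = 0` the fit is the plain kernel ridge
#'   solution at these values).
#' @param max_iter,tol Evidence-update iteration controls.
#' @param grid_step Dense grid spacing in months.
#' @param measure,child_id,speaker_role Optional labels carried on the
#'   result.
#' @return An object of class `dev_curve`; see [tidy.dev_curve()],
#'   [glance.dev_curve()], [autoplot.dev_curve()].
#' @export
fit_bayes_kernel <- function(x, t, sigma, seed = 1, alpha0 = NULL,
                             beta0 = NULL, max_iter = 1000, tol = 1e-6,
                             grid_step = 0.1, measure = NA_character_,
                             child_id = NA_character_,
                             speaker_role = NA_character_) {
  stopifnot(length(x) == length(t))
  if (length(x) < 3) stop("insufficient data for curve fitting")
  if (is.null(alpha0) || is.null(beta0)) {
    init <- local_seed(seed, rlnorm(2, meanlog = 0, sdlog = 2))
    if (is.null(alpha0)) alpha0 <- init[1]
    if (is.null(beta0)) beta0 <- init[2]
  }
  K <- rbf_gram(x, sigma)
  es <- eigen(K, symmetric = TRUE)
  tb <- drop(crossprod(es$vectors, t))
  fit <- evidence_iterate(es$values, tb, alpha0, beta0,
                          max_iter = max_iter, tol = tol)
  if (!fit$converged && max_iter > 0) {
    warning("evidence updates did not converge within ", max_iter,
            " iterations (measure: ", measure, ")", call. = FALSE)
  }
  m <- drop(es$vectors %*% fit$d)
  grid <- seq(min(x), max(x), by = grid_step)
  fitted <- drop(rbf_gram(grid, sigma, x) %*% m)
  fitted_at_train <- drop(K %*% m)
  normalized_defined <- max(fitted) > 0
  normalized <- if (normalized_defined) fitted / max(fitted) else
    rep(NA_real_, length(fitted))
  structure(
    list(
      measure = measure, child_id = child_id, speaker_role = speaker_role,
      train_months = x, train_values = t, sigma = sigma,
      alpha = fit$alpha, beta = fit$beta, weights = m, grid = grid,
      fitted = fitted, fitted_at_train = fitted_at_train,
      r2 = if (length(x) >= 2) r_squared(t, fitted_at_train) else NA_real_,
      normalized = normalized, normalized_defined = normalized_defined,
      converged = fit$converged, iterations = fit$iter, seed = seed
    ),
    class = "dev_curve"
  )
}

#' Select the kernel width by leave-one-out cross-validation
#'
#' For each candidate width, each observation is left out in turn, the
#' model is refitted on the rest — hyperparameters re-estimated within the
#' fold by the same evidence updates, warm-started from the full-data
#' converged values (the evidence fixed point does not depend on the
#' starting point on well-conditioned data, and warm starts make the
#' selection deterministic and fast) — and the left-out value is
#' predicted. The width minimizing the mean squared leave-one-out error
#' is returned (smallest such width on ties).
#'
#' @inheritParams fit_bayes_kernel
#' @param sigma_grid Candidate widths (months), all positive.
#' @param max_iter,tol Per-fold evidence-update controls.
#' @return A single width from `sigma_grid`.
#' @export
select_sigma_loocv <- function(x, t, sigma_grid = default_sigma_grid(),
                               max_iter = 500, tol = 1e-6) {
  stopifnot(length(x) == length(t))
  if (length(x) < 3) stop("insufficient data for curve fitting")
  if (any(sigma_grid <= 0)) stop("sigma grid must be positive")
  n <- length(x)
  errs <- vapply(sigma_grid, function(sigma) {
    K <- rbf_gram(x, sigma)
    es <- eigen(K, symmetric = TRUE)
    tb <- drop(crossprod(es$vectors, t))
    full <- evidence_iterate(es$values, tb, 1, 1, max_iter = max_iter,
                             tol = tol)
    se <- vapply(seq_len(n), function(i) {
      Ki <- K[-i, -i, drop = FALSE]
      esi <- eigen(Ki, symmetric = TRUE)
      tbi <- drop(crossprod(esi$vectors, t[-i]))
      fi <- evidence_iterate(esi$values, tbi, full$alpha, full$beta,
                             max_iter = max_iter, tol = tol)
      mi <- drop(esi$vectors %*% fi$d)
      pred <- sum(K[i, -i] * mi)
      (t[i] - pred)^2
    }, numeric(1))
    mean(se)
  }, numeric(1))
  sigma_grid[which.min(errs)]
}

#' Fit a developmental curve to an index series
#'
#' Tidy front door to the kernel regression: takes an index-series data
#' frame (one measure, one child or pooled series), selects the kernel
#' width by leave-one-out cross-validation unless `sigma` is given, and
#' fits the Bayesian RBF model.
#'
#' @param data Data frame with the columns named by `month` and `value`
#'   (defaults match [compute_indices()] output); optional `measure`,
#'   `child_id`, `speaker_role` columns label the result when constant.
#' @param month,value Column names (tidy evaluation).
#' @param sigma Kernel width; `NULL` (default) triggers LOOCV selection
#'   over `sigma_grid`.
#' @inheritParams fit_bayes_kernel
#' @inheritParams select_sigma_loocv
#' @return A `dev_curve`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(month = 7:40,
#'                     value = plogis((month - 20) / 3) + rnorm(34, 0, 0.05))
#' fit <- fit_dev_curve(d, sigma = 5)
#' glance(fit)
fit_dev_curve <- function(data, month = "month", value = "value",
                          sigma = NULL, sigma_grid = default_sigma_grid(),
                          seed = 1, grid_step = 0.1, max_iter = 1000,
                          tol = 1e-6) {
  x <- data[[month]]
  t <- data[[value]]
  label <- function(col) {
    if (col %in% names(data) && length(unique(data[[col]])) == 1) {
      data[[col]][1]
    } else {
      NA_character_
    }
  }
  if (is.null(sigma)) {
    sigma <- select_sigma_loocv(x, t, sigma_grid, max_iter = max_iter,
                                tol = tol)
  }
  fit_bayes_kernel(x, t, sigma, seed = seed, max_iter = max_iter,
                   tol = tol, grid_step = grid_step,
                   measure = label("measure"), child_id = label("child_id"),
                   speaker_role = label("speaker_role"))
}

#' Max-normalize a fitted curve
#'
#' Divides the fitted grid trajectory by its maximum so threshold-based
#' onset/offset detection operates on a curve peaking at 1. When the
#' maximum is not positive the normalized curve is undefined and flagged
#' (`normalized_defined = FALSE`).
#'
#' @param curve A `dev_curve`.
#' @return The curve with `normalized` (re)computed.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "dev_curve"))
  mx <- max(curve$fitted)
  curve$normalized_defined <- mx > 0
  curve$normalized <- if (curve$normalized_defined) curve$fitted / mx else
    rep(NA_real_, length(curve$fitted))
  curve
}

#' @export
print.dev_curve <- function(x, ...) {
  cat("<dev_curve>",
      if (!is.na(x$measure)) paste0(" measure=", x$measure) else "",
      "\n  n=", length(x$train_months),
      " months [", min(x$train_months), ", ", max(x$train_months), "]",
      "\n  sigma=", signif(x$sigma, 4),
      "  alpha=", signif(x$alpha, 4),
      "  beta=", signif(x$beta, 4),
      "  R2=", signif(x$r2, 4),
      if (!x$converged) "  (not converged)" else "",
      "\n", sep = "")
  invisible(x)
}
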