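test_that("RBF Gram matrix has the closed form and is PSD", {
  expect_equal(rbf_gram(0, 1), matrix(1, 1, 1))
  K <- rbf_gram(c(0, sqrt(2) * 3), sigma = 3)
  expect_equal(K[1, 2], exp(-1))
  expect_equal(diag(K), c(1, 1))
  expect_error(rbf_gram(1:3, 0), "positive")
  expect_error(rbf_gram(1:3, -2), "positive")

  set.seed(11)
  for (i in 1:5) {
    x <- sort(runif(15, 0, 60))
    K <- rbf_gram(x, sigma = runif(1, 0.5, 20))
    expect_equal(K, t(K))
    expect_true(min(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("r_squared covers perfect, mean and worse-than-mean predictors", {
  obs <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_lt(r_squared(obs, -obs), 0)
  expect_true(is.na(r_squared(rep(2, 4), c(1, 2, 3, 2))))
})

test_that("posterior mean at fixed hyperparameters equals kernel ridge", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(5:20, 1)
    x <- sort(runif(n, 0, 60))
    t <- sin(x / 8) + rnorm(n, 0, 0.2)
    sigma <- runif(1, 1, 15)
    alpha <- runif(1, 0.01, 5)
    beta <- runif(1, 0.5, 50)
    fit <- fit_bayes_kernel(x, t, sigma, alpha0 = alpha, beta0 = beta,
                            max_iter = 0)
    K <- rbf_gram(x, sigma)
    ridge <- solve(crossprod(K) + (alpha / beta) * diag(n), crossprod(K, t))
    expect_equal(fit$weights, drop(ridge), tolerance = 1e-8)
    expect_equal(fit$fitted_at_train, drop(K %*% ridge), tolerance = 1e-8)
  }
})

test_that("noise-free data in the model class is fit almost exactly", {
  x <- seq(5, 40, by = 2.5)
  K <- rbf_gram(x, sigma = 6)
  t <- drop(K %*% c(rep(0, 4), 2, rep(0, length(x) - 5)))  # one basis column
  fit <- fit_bayes_kernel(x, t, sigma = 6, seed = 5, tol = 1e-10,
                          max_iter = 5000)
  expect_equal(fit$fitted_at_train, t, tolerance = 1e-6)
  expect_gt(fit$r2, 0.999)
})

test_that("converged hyperparameters do not depend on the initialization", {
  set.seed(33)
  x <- seq(7, 60, by = 1)
  t <- plogis((x - 25) / 5) + rnorm(length(x), 0, 0.05)
  fits <- lapply(c(2, 97), function(s) {
    fit_bayes_kernel(x, t, sigma = 6, seed = s, tol = 1e-9,
                     max_iter = 5000)
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  expect_equal(fits[[1]]$alpha, fits[[2]]$alpha, tolerance = 1e-4)
  expect_equal(fits[[1]]$beta, fits[[2]]$beta, tolerance = 1e-4)
  expect_equal(fits[[1]]$fitted, fits[[2]]$fitted, tolerance = 1e-6)
})

test_that("increasing the weight precision never increases the weight norm", {
  set.seed(55)
  for (i in 1:4) {
    x <- sort(runif(12, 0, 40))
    t <- cos(x / 5) + rnorm(12, 0, 0.1)
    alphas <- sort(runif(6, 0.001, 20))
    norms <- vapply(alphas, function(a) {
      fit <- fit_bayes_kernel(x, t, sigma = 4, alpha0 = a, beta0 = 10,
                              max_iter = 0)
      sum(fit$weights^2)
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-12))
  }
})

test_that("LOOCV picks wide kernels for smooth trends, narrow for fine structure", {
  set.seed(77)
  x <- seq(7, 60, by = 1)
  smooth <- 0.01 * x + rnorm(length(x), 0, 0.01)
  wiggly <- sin(x * 2) * 0.5 + rnorm(length(x), 0, 0.01)
  grid <- default_sigma_grid(k = 10)
  sig_smooth <- select_sigma_loocv(x, smooth, grid)
  sig_wiggly <- select_sigma_loocv(x, wiggly, grid)
  expect_gt(sig_smooth, sig_wiggly)
  expect_gte(sig_smooth, grid[7])  # at the wide end for a linear trend

  # duplicated observations do not break the selection
  sig_dup <- select_sigma_loocv(c(x, x[1]), c(smooth, smooth[1]), grid)
  expect_true(sig_dup %in% grid)

  expect_error(select_sigma_loocv(c(1, 2), c(0, 1)), "insufficient data")
  expect_error(fit_bayes_kernel(c(1, 2), c(0, 1), 1), "insufficient data")
  expect_error(select_sigma_loocv(x, smooth, c(-1, 2)), "positive")
})

test_that("normalization divides by the curve maximum when positive", {
  x <- seq(0, 30, by = 1)
  t <- plogis((x - 15) / 3)
  fit <- fit_dev_curve(tibble::tibble(month = x, value = t), sigma = 4)
  expect_equal(max(fit$normalized), 1)
  expect_equal(fit$normalized, fit$fitted / max(fit$fitted))
  renorm <- normalize_curve(fit)
  expect_equal(renorm$normalized, fit$normalized)

  # negative-everywhere curves have no defined normalization
  fit_neg <- fit_dev_curve(tibble::tibble(month = x, value = -1 - t),
                           sigma = 4)
  expect_false(fit_neg$normalized_defined)
  expect_true(all(is.na(fit_neg$normalized)))
  expect_error(detect_onset_offset(fit_neg), "not positive")
})

test_that("glance, tidy, augment and autoplot expose the fit", {
  d <- tibble::tibble(month = seq(7, 30, by = 1),
                      value = plogis((seq(7, 30, by = 1) - 18) / 3),
                      measure = "intra", child_id = "B",
                      speaker_role = "child")
  fit <- fit_dev_curve(d, sigma = 5, seed = 9)
  g <- glance(fit)
  expect_equal(g$measure, "intra")
  expect_equal(g$n_obs, 24L)
  expect_equal(g$sigma, 5)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$grid))
  expect_named(td, c("month", "fitted", "normalized"))
  au <- augment(fit)
  expect_equal(au$.resid, au$value - au$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, normalized = TRUE), "ggplot")
})
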