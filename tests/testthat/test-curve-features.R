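# Build a dev_curve by hand so feature detection can be tested against
# analytic trajectories, independently of the regression step.
manual_curve <- function(grid, fitted, measure = "test") {
  structure(
    list(measure = measure, child_id = "A", speaker_role = "child",
         train_months = grid, train_values = fitted, sigma = 1,
         alpha = 1, beta = 1, weights = NULL, grid = grid, fitted = fitted,
         fitted_at_train = fitted, r2 = 1,
         normalized = fitted / max(fitted),
         normalized_defined = max(fitted) > 0, converged = TRUE,
         iterations = 0, seed = 1),
    class = "dev_curve"
  )
}

test_that("a linear ramp crosses 1/3 and 2/3 where arithmetic says", {
  g <- seq(0, 30, by = 0.1)
  ramp <- manual_curve(g, g / 30)
  f <- detect_onset_offset(ramp)
  expect_equal(f$onset_month, 10, tolerance = 1e-6)
  expect_equal(f$offset_month, 20, tolerance = 1e-6)
  expect_equal(f$duration_months, 10, tolerance = 1e-6)
  expect_true(f$stays_above_onset)
  expect_true(f$stays_above_offset)
})

test_that("curves already above 2/3 get degenerate zero-length change", {
  g <- seq(5, 20, by = 0.1)
  high <- manual_curve(g, 0.9 + 0.1 * (g - 5) / 15)
  f <- detect_onset_offset(high)
  expect_equal(f$onset_month, 5)
  expect_equal(f$offset_month, 5)
  expect_equal(f$duration_months, 0)
})

test_that("curves that never reach a threshold report it as not reached", {
  g <- seq(0, 30, by = 0.1)
  # normalized curve rising from 0.5 to 1: onset degenerate, offset real
  f <- detect_onset_offset(manual_curve(g, 0.5 + 0.5 * g / 30))
  expect_equal(f$onset_month, 0)
  expect_gt(f$offset_month, 0)
  # mirror a curve peaking below: normalized always 0..1, but thresholds
  # on the raw scale can be exposed via custom thresholds
  f2 <- detect_onset_offset(manual_curve(g, g / 30),
                            offset_threshold = 1.5)
  expect_true(is.na(f2$offset_month))
  expect_true(is.na(f2$duration_months))
})

test_that("logistic crossings match the closed-form inverse", {
  g <- seq(0, 60, by = 0.1)
  mid <- 22; slope <- 0.4
  y <- plogis(slope * (g - mid))
  curve <- manual_curve(g, y)
  # normalized by max = plogis(slope*(60-mid)); invert analytically
  mx <- plogis(slope * (60 - mid))
  inv <- function(p) mid + qlogis(p * mx) / slope
  f <- detect_onset_offset(curve)
  expect_equal(f$onset_month, inv(1 / 3), tolerance = 0.1)
  expect_equal(f$offset_month, inv(2 / 3), tolerance = 0.1)
})

test_that("first-crossing semantics: later dips do not move the onset", {
  g <- seq(0, 30, by = 0.1)
  y <- 0.2 + 0.6 * exp(-(g - 10)^2 / 8) + 0.8 * exp(-(g - 25)^2 / 8)
  curve <- manual_curve(g, y)
  f <- detect_onset_offset(curve)
  expect_lt(f$onset_month, 10)
  expect_false(f$stays_above_onset)
})

test_that("onset precedes offset for monotone nondecreasing curves", {
  set.seed(91)
  g <- seq(0, 40, by = 0.1)
  for (i in 1:10) {
    y <- cumsum(runif(length(g)))
    f <- detect_onset_offset(manual_curve(g, y))
    expect_lte(f$onset_month, f$offset_month)
    expect_equal(f$duration_months, f$offset_month - f$onset_month)
  }
})

test_that("intersections are located by sign change with interpolation", {
  g <- seq(0, 30, by = 0.1)
  rising <- manual_curve(g, g / 30, measure = "inter_LC")
  ref <- manual_curve(g, rep(1, length(g)), measure = "intra")
  ref$normalized <- rep(0.5, length(g))  # constant reference at 0.5
  hit <- find_intersection(rising, ref)
  expect_equal(hit$month, 15, tolerance = 1e-6)
  expect_equal(hit$rising_measure, "inter_LC")
  expect_equal(hit$reference_measure, "intra")

  low <- manual_curve(g, 0.2 + 0 * g)
  expect_true(is.na(find_intersection(low, ref)$month))

  other_grid <- manual_curve(seq(0, 20, by = 0.1), seq(0, 20, by = 0.1))
  expect_error(find_intersection(rising, other_grid), "same grid")
})

test_that("two analytic curves cross where root finding says they do", {
  g <- seq(0, 40, by = 0.1)
  f1 <- function(t) plogis((t - 20) / 2)
  f2 <- function(t) 0.4 + 0.01 * t
  root <- uniroot(function(t) f1(t) - f2(t), c(5, 30), tol = 1e-10)$root
  hit <- find_intersection(
    manual_curve(g, f1(g)) |> (\(cv) { cv$normalized <- f1(g); cv })(),
    manual_curve(g, f2(g)) |> (\(cv) { cv$normalized <- f2(g); cv })()
  )
  expect_equal(hit$month, root, tolerance = 0.1)
})

test_that("peaks are reported at the maximum, first occurrence on ties", {
  g <- seq(0, 40, by = 0.1)
  bump <- manual_curve(g, exp(-(g - 25)^2 / 20))
  expect_equal(find_peak(bump), 25, tolerance = 0.1 + 1e-9)
  mono <- manual_curve(g, g)
  expect_equal(find_peak(mono), 40)
  flat <- manual_curve(g, rep(2, length(g)))
  expect_equal(find_peak(flat), 0)
})
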