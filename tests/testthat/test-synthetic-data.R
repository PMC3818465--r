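# A trajectory in which the intra-organ measure is a pure logistic:
# CD = DC follow a logistic and LL absorbs the complement, so the
# category probabilities need no renormalization and the intra ratio is
# 2 * CD(t) exactly.
logistic_intra_spec <- function(f, c, m, s) {
  trajectory_spec(
    tibble::tribble(
      ~category, ~floor, ~ceiling, ~midpoint, ~slope,
      "LL", 1 - 2 * c, 1 - 2 * f, m, -s,
      "CC", 0, 0, 20, 1,
      "DD", 0, 0, 20, 1,
      "CD", f, c, m, s,
      "DC", f, c, m, s,
      "LC", 0, 0, 20, 1,
      "LD", 0, 0, 20, 1,
      "CL", 0, 0, 20, 1,
      "DL", 0, 0, 20, 1
    ),
    rho = NULL, mirror = character()
  )
}

test_that("category probabilities are a valid simplex at every month", {
  spec <- trajectory_paperlike()
  t <- seq(7, 60, by = 0.5)
  w <- category_weights(spec, t)
  expect_true(all(w >= 0))
  p <- category_probs(spec, t)
  expect_equal(rowSums(p), rep(1, length(t)))
  expect_equal(colnames(p), cvc_categories())
  # backing partners are the mirrored fronting weights scaled by rho <= 1
  expect_true(all(w[, "CL"] <= w[, "LC"] + 1e-12))
  expect_true(all(w[, "DL"] <= w[, "LD"] + 1e-12))
})

test_that("a degenerate all-repetition generator gives repetition ratio 1", {
  spec <- logistic_intra_spec(0, 0, 17, 0.25)  # all mass on LL
  cfg <- sim_config(children = 1, months = 10:14, tokens_per_month = 20,
                    trajectory = spec, seed = 4)
  corpus <- simulate_corpus(cfg)
  units <- extract_cvc_units(corpus)
  expect_true(all(units$category == "LL"))
  counts <- count_monthly(units, pool = TRUE)
  expect_true(all(repetition_ratio(counts) == 1))
})

test_that("symmetric fronting weights give a near-zero fronting index", {
  spec <- trajectory_spec(
    tibble::tribble(
      ~category, ~floor, ~ceiling, ~midpoint, ~slope,
      "LL", 0, 0, 20, 1, "CC", 0, 0, 20, 1, "DD", 0, 0, 20, 1,
      "CD", 0, 0, 20, 1, "DC", 0, 0, 20, 1,
      "LC", 0.5, 0.5, 20, 1, "CL", 0.5, 0.5, 20, 1,
      "LD", 0, 0, 20, 1, "DL", 0, 0, 20, 1
    ),
    rho = NULL, mirror = character()
  )
  cfg <- sim_config(children = 1, months = 12, tokens_per_month = 10000,
                    trajectory = spec, seed = 8)
  counts <- simulate_corpus(cfg) |>
    extract_cvc_units() |>
    count_monthly(pool = TRUE)
  # a + b = n, so the index has standard error 1/sqrt(n) under symmetry
  expect_lt(abs(fronting_index(counts)), 3 / sqrt(10000))
})

test_that("identical seeds reproduce the corpus byte for byte", {
  cfg <- sim_config(children = 2, months = 10:15, tokens_per_month = 10,
                    seed = 99)
  c1 <- simulate_corpus(cfg)
  c2 <- simulate_corpus(cfg)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_corpus_tsv(c1, p1)
  write_corpus_tsv(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  cfg2 <- cfg
  cfg2$seed <- 100
  expect_false(identical(simulate_corpus(cfg2), c1))
})

test_that("empirical category frequencies converge to the generator's", {
  spec <- trajectory_paperlike()
  cfg <- sim_config(children = 1, months = 20, tokens_per_month = 10000,
                    trajectory = spec, seed = 12)
  counts <- simulate_corpus(cfg) |>
    extract_cvc_units() |>
    count_monthly(pool = TRUE)
  p_hat <- as.numeric(counts[1, cvc_categories()]) / counts$total
  p <- drop(category_probs(spec, 20))
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(p_hat - p) < pmax(4 * se, 1e-3)))
})

test_that("simulated durations follow the inverted-U with unit-mean noise", {
  cfg <- sim_config(children = 1, months = c(7, 18, 40),
                    tokens_per_month = 2000, seed = 31)
  durs <- simulate_corpus(cfg) |> extract_cvcv_durations()
  by_month <- mean_cvcv_duration(durs)
  # total CVCV duration: base 400 ms, peak 600 ms at 18 months
  expect_equal(by_month$value[by_month$month == 18], 600, tolerance = 0.02)
  expect_lt(by_month$value[by_month$month == 40],
            by_month$value[by_month$month == 18])
  expect_equal(by_month$value[by_month$month == 7],
               400 + 200 * exp(-(7 - 18)^2 / (2 * 8^2)), tolerance = 0.02)
})

test_that("true crossings agree with the closed-form logistic inverse", {
  f <- 0.01; cl <- 0.45; m <- 17; s <- 0.25
  spec <- logistic_intra_spec(f, cl, m, s)
  cfg <- sim_config(trajectory = spec)
  tf <- true_features(cfg, measures = "intra")
  # intra(t) = 2 * (f + (cl - f) * plogis(s (t - m))): invert analytically
  intra_at <- function(t) 2 * (f + (cl - f) * plogis(s * (t - m)))
  mx <- intra_at(60)
  inv <- function(q) m + qlogis((q * mx / 2 - f) / (cl - f)) / s
  expect_equal(tf$onset_month, inv(1 / 3), tolerance = 1e-6)
  expect_equal(tf$offset_month, inv(2 / 3), tolerance = 1e-6)
  expect_equal(tf$duration_months, inv(2 / 3) - inv(1 / 3),
               tolerance = 1e-6)
})

test_that("a trajectory crossing at chosen months reports the chosen duration", {
  # choose the slope so the normalized logistic first exceeds 1/3 at 8.5
  # months; the offset and duration then follow from the same inverse
  m <- 16.75
  crossing <- function(s, q) {
    mx <- plogis(s * (60 - m))
    m + qlogis(q * mx) / s
  }
  s <- uniroot(function(s) crossing(s, 1 / 3) - 8.5, c(0.01, 1),
               tol = 1e-12)$root
  spec <- logistic_intra_spec(0, 0.45, m, s)
  # scale to the pure-logistic normalized curve: floor 0 keeps intra(t)
  # proportional to plogis(s (t - m))
  cfg <- sim_config(trajectory = spec)
  tf <- true_features(cfg, measures = "intra")
  expect_equal(tf$onset_month, 8.5, tolerance = 1e-6)
  expect_equal(tf$duration_months, crossing(s, 2 / 3) - 8.5,
               tolerance = 1e-6)
})

test_that("non-crossing trajectories report features as absent", {
  spec <- logistic_intra_spec(0.2, 0.21, 17, 0.25)
  cfg <- sim_config(trajectory = spec)
  tf <- true_features(cfg, measures = "intra",
                      offset_threshold = 2)  # unreachable threshold
  expect_true(is.na(tf$offset_month))
})

test_that("true intersection months agree with direct root finding", {
  cfg <- sim_config()
  hits <- true_intersections(cfg)
  expect_equal(hits$rising_measure, c("inter_LC", "inter_LD"))
  ts <- seq(7, 60, by = 0.001)
  for (i in seq_len(nrow(hits))) {
    ms <- hits$rising_measure[i]
    ri <- measure_trajectory(cfg$trajectory, ms, ts)
    re <- measure_trajectory(cfg$trajectory, "intra", ts)
    d <- ri / max(ri) - re / max(re)
    brute <- ts[which(d[-1] >= 0 & d[-length(d)] < 0)[1] + 1]
    expect_equal(hits$month[i], brute, tolerance = 0.01)
  }
})
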