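# Synthetic babbling-corpus generator. Each child-month draws CVC
# category labels from a multinomial whose probabilities follow smooth
# logistic trajectories over age, realized as concrete CVCV strings; the
# implied measure trajectories (and their threshold crossings) are
# available in closed form, so the whole pipeline can be tested by
# parameter recovery without any corpus download.

logistic_at <- function(t, floor, ceiling, midpoint, slope) {
  floor + (ceiling - floor) * plogis(slope * (t - midpoint))
}

#' Construct a trajectory specification
#'
#' Per-category weight functions over month of age `t`: each of the nine
#' CVC categories follows a four-parameter logistic
#' `floor + (ceiling - floor) * plogis(slope * (t - midpoint))`
#' (negative slopes give decreasing trajectories). Categories listed in
#' `mirror` (by default the backing members CL and DL) take the weight of
#' their mirrored fronting partner multiplied by the fronting-asymmetry
#' factor `rho(t) <= 1`, itself a rising logistic with floor `rho$floor`:
#' early on, back-to-front orderings are suppressed by the factor `rho`,
#' and the asymmetry vanishes as `rho` approaches 1. Category
#' probabilities at month `t` are the weights normalized to sum to 1.
#'
#' @param params Data frame with columns `category`, `floor`, `ceiling`,
#'   `midpoint`, `slope`, one row per non-mirrored category.
#' @param rho List `(floor, midpoint, slope)` for the asymmetry factor, or
#'   `NULL` when `mirror` is empty.
#' @param mirror Named character vector mapping mirrored categories to
#'   their source (default `c(CL = "LC", DL = "LD")`).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(params, rho = NULL,
                            mirror = c(CL = "LC", DL = "LD")) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("category", "floor", "ceiling", "midpoint", "slope") %in%
                  names(params)))
  need <- setdiff(cvc_categories(), names(mirror))
  missing <- setdiff(need, params$category)
  if (length(missing)) {
    stop("trajectory parameters missing for: ",
         paste(missing, collapse = ", "))
  }
  if (length(mirror) && is.null(rho)) {
    stop("mirrored categories require a rho specification")
  }
  structure(list(params = params, rho = rho, mirror = mirror),
            class = "trajectory_spec")
}

#' The "paperlike" preset trajectory
#'
#' Encodes the qualitative developmental structure the analysis assumes:
#' repetition categories (LL, CC, DD) dominate early (about 95% of
#' probability mass before 12 months) and decay after about 18 months;
#' intra-organ categories (CD, DC) rise slowly and symmetrically from
#' about 17 months; inter-organ fronting categories (LC, LD) rise steeply
#' with later midpoints (around 19-20 months); their backing partners
#' (CL, DL) mirror them scaled by a fronting asymmetry of about 0.3 early
#' that vanishes by roughly 24 months. This yields an early repetition
#' plateau, a transient fronting-index bump peaking in the mid-teens,
#' a shallow early-onset intra-organ rise and steep late-onset inter-organ
#' rises — intra onset before inter onsets, inter durations shorter.
#'
#' @return A `trajectory_spec`.
#' @export
trajectory_paperlike <- function() {
  params <- tibble::tribble(
    ~category, ~floor, ~ceiling, ~midpoint, ~slope,
    "LL", 0.050, 0.400, 20, -0.35,
    "CC", 0.060, 0.380, 20, -0.35,
    "DD", 0.030, 0.170, 20, -0.35,
    "CD", 0.010, 0.100, 17, 0.25,
    "DC", 0.010, 0.100, 17, 0.25,
    "LC", 0.0005, 0.180, 20, 0.60,
    "LD", 0.0005, 0.120, 19, 0.60
  )
  trajectory_spec(params, rho = list(floor = 0.3, midpoint = 19,
                                     slope = 0.45))
}

rho_at <- function(spec, t) {
  if (is.null(spec$rho)) return(rep(1, length(t)))
  logistic_at(t, spec$rho$floor, 1, spec$rho$midpoint, spec$rho$slope)
}

#' Category weights and probabilities at given months
#'
#' @param spec A `trajectory_spec`.
#' @param t Numeric vector of months.
#' @return A `length(t)` by 9 matrix with columns in [cvc_categories()]
#'   order; `category_probs()` rows sum to 1.
#' @export
category_weights <- function(spec, t) {
  cats <- cvc_categories()
  w <- matrix(0, nrow = length(t), ncol = length(cats),
              dimnames = list(NULL, cats))
  for (i in seq_len(nrow(spec$params))) {
    p <- spec$params[i, ]
    w[, p$category] <- logistic_at(t, p$floor, p$ceiling, p$midpoint,
                                   p$slope)
  }
  if (length(spec$mirror)) {
    r <- rho_at(spec, t)
    for (cat in names(spec$mirror)) {
      w[, cat] <- r * w[, spec$mirror[[cat]]]
    }
  }
  if (any(w < 0)) stop("trajectory weights must be nonnegative")
  w
}

#' @rdname category_weights
#' @export
category_probs <- function(spec, t) {
  w <- category_weights(spec, t)
  sweep(w, 1, rowSums(w), "/")
}

#' Simulation configuration
#'
#' Bundles the study design of a synthetic corpus: number of children,
#' observed month range, tokens recorded per child per month, the
#' category-probability trajectory, and an inverted-U CVCV duration model
#' (total CVCV duration rising from `duration_base_ms` to
#' `duration_peak_ms` around `duration_peak_month` with Gaussian width
#' `duration_width`, multiplicative log-normal noise of coefficient of
#' variation `duration_cv` per phoneme).
#'
#' @param children Number of children.
#' @param months Integer months of age covered (default 7 to 60).
#' @param tokens_per_month CVCV tokens per child per month, a single
#'   number or a vector along `months`.
#' @param trajectory A `trajectory_spec`.
#' @param duration_base_ms,duration_peak_ms,duration_peak_month,duration_width
#'   Duration-model parameters (total milliseconds for the 4-phoneme CVCV).
#' @param duration_cv Per-phoneme multiplicative noise CV.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(children = 3, months = 7:60, tokens_per_month = 50,
                       trajectory = trajectory_paperlike(),
                       duration_base_ms = 400, duration_peak_ms = 600,
                       duration_peak_month = 18, duration_width = 8,
                       duration_cv = 0.15, seed = 1) {
  stopifnot(inherits(trajectory, "trajectory_spec"),
            all(tokens_per_month >= 0))
  tokens_per_month <- rep_len(tokens_per_month, length(months))
  structure(
    list(children = children, months = as.integer(months),
         tokens_per_month = tokens_per_month, trajectory = trajectory,
         duration_base_ms = duration_base_ms,
         duration_peak_ms = duration_peak_ms,
         duration_peak_month = duration_peak_month,
         duration_width = duration_width, duration_cv = duration_cv,
         seed = seed),
    class = "sim_config"
  )
}

cvcv_mean_duration_at <- function(cfg, t) {
  cfg$duration_base_ms +
    (cfg$duration_peak_ms - cfg$duration_base_ms) *
    exp(-(t - cfg$duration_peak_month)^2 / (2 * cfg$duration_width^2))
}

#' Simulate a synthetic corpus
#'
#' For each child and month, draws `tokens_per_month` category labels from
#' the month's multinomial and realizes each as a concrete CVCV utterance:
#' a uniformly chosen consonant of each required place, uniformly chosen
#' vowels, and per-phoneme durations from the inverted-U duration model
#' with multiplicative log-normal noise (unit mean). The generator is
#' fully seeded: identical configurations produce identical corpora.
#'
#' @param cfg A [sim_config()].
#' @param table Consonant table supplying the place inventories and vowel
#'   set used to realize tokens.
#' @return A corpus tibble, directly consumable by [extract_cvc_units()].
#' @export
simulate_corpus <- function(cfg, table = default_consonant_table()) {
  stopifnot(inherits(cfg, "sim_config"))
  cats <- cvc_categories()
  by_place <- split(table$consonants$phoneme, table$consonants$place)
  vowels <- c("a", "i", "u", "e", "o")
  vowels <- vowels[vowels %in% table$vowels]
  if (!length(vowels)) vowels <- table$vowels
  place_name <- c(L = "labial", C = "coronal", D = "dorsal")
  sdlog <- sqrt(log(1 + cfg$duration_cv^2))

  local_seed(cfg$seed, {
    rows <- list()
    for (child in seq_len(cfg$children)) {
      cid <- sprintf("sim%02d", child)
      for (k in seq_along(cfg$months)) {
        m <- cfg$months[k]
        n_tok <- cfg$tokens_per_month[k]
        if (n_tok == 0) next
        p <- drop(category_probs(cfg$trajectory, m))
        draws <- drop(rmultinom(1, n_tok, p))
        labels <- rep(cats, draws)
        if (!length(labels)) next
        p1 <- place_name[substr(labels, 1, 1)]
        p2 <- place_name[substr(labels, 2, 2)]
        c1 <- vapply(p1, function(pl) sample(by_place[[pl]], 1),
                     character(1), USE.NAMES = FALSE)
        c2 <- vapply(p2, function(pl) sample(by_place[[pl]], 1),
                     character(1), USE.NAMES = FALSE)
        v1 <- sample(vowels, length(labels), replace = TRUE)
        v2 <- sample(vowels, length(labels), replace = TRUE)
        mu_ph <- cvcv_mean_duration_at(cfg, m) / 4
        noise <- matrix(
          exp(rnorm(4 * length(labels), -sdlog^2 / 2, sdlog)),
          ncol = 4
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          child_id = cid, speaker_role = "child", age_months = m,
          phonemes = purrr::pmap(list(c1, v1, c2, v2), c),
          durations_ms = lapply(seq_along(labels), function(j) {
            mu_ph * noise[j, ]
          })
        )
      }
    }
    if (!length(rows)) new_corpus() else purrr::list_rbind(rows)
  })
}

#' Analytic measure trajectories implied by a trajectory specification
#'
#' The closed-form value of a developmental measure at months `t`, as
#' implied by the category probabilities of the generator (the exact
#' large-sample limit of the empirical per-month indices).
#'
#' @param spec A `trajectory_spec`.
#' @param measure One of `"repetition"`, `"fronting"`, `"intra"`,
#'   `"inter_LC"`, `"inter_LD"`.
#' @param t Numeric vector of months.
#' @return Numeric vector of measure values.
#' @export
measure_trajectory <- function(spec, measure, t) {
  p <- category_probs(spec, t)
  switch(
    measure,
    repetition = p[, "LL"] + p[, "CC"] + p[, "DD"],
    fronting = {
      a <- p[, "LC"] + p[, "LD"] + p[, "CD"]
      b <- p[, "CL"] + p[, "DL"] + p[, "DC"]
      (a - b) / (a + b)
    },
    intra = p[, "CD"] + p[, "DC"],
    inter_LC = p[, "LC"] + p[, "CL"],
    inter_LD = p[, "LD"] + p[, "DL"],
    stop("unknown measure: ", measure)
  )
}

RECOVERY_MEASURES <- c("repetition", "fronting", "intra", "inter_LC",
                       "inter_LD")

# First month in [lo, hi] where f exceeds `threshold`, located by a fine
# scan and refined by uniroot on the bracketing interval; NA if never
# exceeded. Matches the first-exceedance semantics of
# detect_onset_offset(), but operates on the analytic function itself.
analytic_first_exceedance <- function(f, lo, hi, threshold,
                                      scan_step = 0.01) {
  ts <- seq(lo, hi, by = scan_step)
  ys <- f(ts)
  above <- ys > threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(lo)
  uniroot(function(t) f(t) - threshold, lower = ts[i - 1], upper = ts[i],
          tol = 1e-9)$root
}

#' Ground-truth developmental features of a simulation configuration
#'
#' Computes, from the analytic measure trajectories, the exact features
#' the pipeline is supposed to recover: for each measure, the months at
#' which the max-normalized trajectory first exceeds the onset and offset
#' thresholds (located by root finding on the closed-form trajectory, to
#' high precision), the implied duration of developmental change, and the
#' peak month.
#'
#' @param cfg A [sim_config()].
#' @param onset_threshold,offset_threshold Analysis thresholds.
#' @param measures Measures to evaluate.
#' @return A tibble `measure`, `onset_month`, `offset_month`,
#'   `duration_months`, `peak_month` (crossings `NA` when never reached
#'   within the month range).
#' @export
true_features <- function(cfg, onset_threshold = 1 / 3,
                          offset_threshold = 2 / 3,
                          measures = RECOVERY_MEASURES) {
  stopifnot(inherits(cfg, "sim_config"))
  lo <- min(cfg$months)
  hi <- max(cfg$months)
  purrr::map(measures, function(ms) {
    f <- function(t) measure_trajectory(cfg$trajectory, ms, t)
    ts <- seq(lo, hi, by = 0.01)
    ys <- f(ts)
    mx <- max(ys)
    if (mx <= 0) {
      return(tibble::tibble(measure = ms, onset_month = NA_real_,
                            offset_month = NA_real_,
                            duration_months = NA_real_,
                            peak_month = NA_real_))
    }
    g <- function(t) f(t) / mx
    onset <- analytic_first_exceedance(g, lo, hi, onset_threshold)
    offset <- analytic_first_exceedance(g, lo, hi, offset_threshold)
    tibble::tibble(
      measure = ms, onset_month = onset, offset_month = offset,
      duration_months = offset - onset,
      peak_month = ts[which.max(ys)]
    )
  }) |>
    purrr::list_rbind()
}

#' Ground-truth intersection months between normalized trajectories
#'
#' Exact months at which each max-normalized inter-organ trajectory first
#' overtakes the normalized intra-organ trajectory, computed from the
#' closed-form curves by root finding.
#'
#' @param cfg A [sim_config()].
#' @param rising_measures Measures overtaking the reference.
#' @param reference_measure The reference measure.
#' @return A tibble `rising_measure`, `reference_measure`, `month`.
#' @export
true_intersections <- function(cfg,
                               rising_measures = c("inter_LC", "inter_LD"),
                               reference_measure = "intra") {
  stopifnot(inherits(cfg, "sim_config"))
  lo <- min(cfg$months)
  hi <- max(cfg$months)
  ts <- seq(lo, hi, by = 0.01)
  norm_fun <- function(ms) {
    f <- function(t) measure_trajectory(cfg$trajectory, ms, t)
    mx <- max(f(ts))
    function(t) f(t) / mx
  }
  ref <- norm_fun(reference_measure)
  purrr::map(rising_measures, function(ms) {
    ri <- norm_fun(ms)
    d <- function(t) ri(t) - ref(t)
    ys <- d(ts)
    idx <- which(ys[-1] >= 0 & ys[-length(ys)] < 0)
    month <- if (length(idx)) {
      uniroot(d, lower = ts[idx[1]], upper = ts[idx[1] + 1],
              tol = 1e-9)$root
    } else {
      NA_real_
    }
    tibble::tibble(rising_measure = ms,
                   reference_measure = reference_measure, month = month)
  }) |>
    purrr::list_rbind()
}
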