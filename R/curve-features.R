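# Quantitative developmental features of fitted curves: threshold
# crossings of the max-normalized trajectory (onset > 1/3, offset > 2/3),
# peak month, and intersections between two normalized curves.

# First grid month where y exceeds `threshold`, refined by linear
# interpolation between the bracketing grid points; NA when never
# exceeded. If the curve starts above threshold the first grid month is
# returned (degenerate crossing).
first_exceedance <- function(grid, y, threshold) {
  above <- y > threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(grid[1])
  # linear interpolation between grid[i-1] (<= thr) and grid[i] (> thr)
  g0 <- grid[i - 1]; g1 <- grid[i]
  y0 <- y[i - 1]; y1 <- y[i]
  g0 + (threshold - y0) / (y1 - y0) * (g1 - g0)
}

#' Detect developmental onset, offset and duration from a normalized curve
#'
#' The onset of developmental change is the first month at which the
#' max-normalized curve exceeds `onset_threshold` (default 1/3); the
#' offset is the first month it exceeds `offset_threshold` (default 2/3);
#' the duration of developmental change is their difference. Crossings are
#' refined by linear interpolation between dense-grid points. First-
#' crossing semantics are used throughout: the earliest exceedance counts
#' even if the curve later dips back below, and the columns
#' `stays_above_onset` / `stays_above_offset` report whether it in fact
#' stayed above until the end of the observed range. A curve that starts
#' above a threshold gets that threshold's crossing at the first grid
#' month (duration 0 when both are degenerate); a curve that never crosses
#' gets `NA` ("not reached" within the observed month range — the model
#' does not extrapolate).
#'
#' @param curve A `dev_curve` with a defined normalized trajectory.
#' @param onset_threshold,offset_threshold Analysis constants, exposed for
#'   sensitivity checks.
#' @return A one-row tibble: `measure`, `child_id`, `onset_month`,
#'   `offset_month`, `duration_months`, `peak_month`,
#'   `stays_above_onset`, `stays_above_offset`.
#' @export
detect_onset_offset <- function(curve, onset_threshold = 1 / 3,
                                offset_threshold = 2 / 3) {
  stopifnot(inherits(curve, "dev_curve"))
  if (!curve$normalized_defined) {
    stop("normalized curve undefined (max of fitted curve is not positive)")
  }
  g <- curve$grid
  y <- curve$normalized
  onset <- first_exceedance(g, y, onset_threshold)
  offset <- first_exceedance(g, y, offset_threshold)
  stays <- function(th) {
    above <- y > th
    any(above) && all(above[which(above)[1]:length(above)])
  }
  tibble::tibble(
    measure = curve$measure,
    child_id = curve$child_id,
    onset_month = onset,
    offset_month = offset,
    duration_months = offset - onset,
    peak_month = find_peak(curve),
    stays_above_onset = stays(onset_threshold),
    stays_above_offset = stays(offset_threshold)
  )
}

#' Month at which a rising curve first overtakes a reference curve
#'
#' Finds the first month where the difference between the two normalized
#' curves changes sign from negative to nonnegative (the rising curve was
#' strictly below immediately before), linearly interpolated between grid
#' points. Both curves must share the same dense grid. `NA` when no such
#' crossing occurs in the observed range.
#'
#' @param rising,reference `dev_curve` objects on a common grid.
#' @return A one-row tibble: `month`, `rising_measure`,
#'   `reference_measure`.
#' @export
find_intersection <- function(rising, reference) {
  stopifnot(inherits(rising, "dev_curve"), inherits(reference, "dev_curve"))
  if (length(rising$grid) != length(reference$grid) ||
      any(rising$grid != reference$grid)) {
    stop("curves are not defined on the same grid")
  }
  d <- rising$normalized - reference$normalized
  month <- NA_real_
  idx <- which(d[-1] >= 0 & d[-length(d)] < 0)
  if (length(idx)) {
    i <- idx[1]
    g0 <- rising$grid[i]; g1 <- rising$grid[i + 1]
    month <- if (d[i + 1] == d[i]) g1 else
      g0 + (0 - d[i]) / (d[i + 1] - d[i]) * (g1 - g0)
  }
  tibble::tibble(
    month = month,
    rising_measure = rising$measure,
    reference_measure = reference$measure
  )
}

#' Month of the curve maximum
#'
#' Grid month at which the fitted trajectory attains its maximum (first
#' occurrence on ties).
#'
#' @param curve A `dev_curve`.
#' @return A single month.
#' @export
find_peak <- function(curve) {
  stopifnot(inherits(curve, "dev_curve"))
  curve$grid[which.max(curve$fitted)]
}
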