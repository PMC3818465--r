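# broom-style accessors and ggplot2 methods for fitted curves.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the dense-grid trajectory of a fitted developmental curve
#'
#' @param x A `dev_curve`.
#' @param ... Unused.
#' @return A tibble with one row per grid month: `month`, `fitted`,
#'   `normalized`.
#' @method tidy dev_curve
#' @export
tidy.dev_curve <- function(x, ...) {
  tibble::tibble(month = x$grid, fitted = x$fitted,
                 normalized = x$normalized)
}

#' One-row fit summary of a developmental curve
#'
#' @param x A `dev_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `measure`, `n_obs`, `sigma`, `alpha`,
#'   `beta`, `r2`, `converged`, `iterations`, `seed`.
#' @method glance dev_curve
#' @export
glance.dev_curve <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, n_obs = length(x$train_months), sigma = x$sigma,
    alpha = x$alpha, beta = x$beta, r2 = x$r2, converged = x$converged,
    iterations = x$iterations, seed = x$seed
  )
}

#' Training observations with fitted values and residuals
#'
#' @param x A `dev_curve`.
#' @param ... Unused.
#' @return A tibble: `month`, `value`, `.fitted`, `.resid`.
#' @method augment dev_curve
#' @export
augment.dev_curve <- function(x, ...) {
  tibble::tibble(
    month = x$train_months, value = x$train_values,
    .fitted = x$fitted_at_train,
    .resid = x$train_values - x$fitted_at_train
  )
}

#' Plot a fitted developmental curve
#'
#' Observed monthly values as points and the fitted trajectory as a line;
#' with `normalized = TRUE` the max-normalized curve is drawn together
#' with the onset (1/3) and offset (2/3) threshold lines used for
#' developmental-change detection.
#'
#' @param object A `dev_curve`.
#' @param normalized Draw the max-normalized curve and thresholds?
#' @param thresholds Threshold levels drawn when `normalized = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dev_curve
#' @export
autoplot.dev_curve <- function(object, normalized = FALSE,
                               thresholds = c(1 / 3, 2 / 3), ...) {
  grid_df <- tidy(object)
  obs <- augment(object)
  lab <- if (is.na(object$measure)) "value" else object$measure
  if (normalized) {
    scale <- max(object$fitted)
    p <- ggplot2::ggplot(grid_df, ggplot2::aes(x = .data$month)) +
      ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_point(
        data = dplyr::mutate(obs, value = .data$value / scale),
        ggplot2::aes(y = .data$value), colour = "grey30", alpha = 0.7
      ) +
      ggplot2::geom_line(ggplot2::aes(y = .data$normalized),
                         colour = "#2166ac", linewidth = 0.8) +
      ggplot2::labs(x = "age (months)", y = paste(lab, "(normalized)"))
  } else {
    p <- ggplot2::ggplot(grid_df, ggplot2::aes(x = .data$month)) +
      ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$value),
                          colour = "grey30", alpha = 0.7) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                         colour = "#2166ac", linewidth = 0.8) +
      ggplot2::labs(x = "age (months)", y = lab)
  }
  p + ggplot2::theme_minimal()
}

#' Plot per-month index series
#'
#' Faceted scatter of the raw monthly measures produced by
#' [compute_indices()], point size reflecting the month's token support.
#'
#' @param indices Index-series tibble.
#' @return A ggplot object.
#' @export
plot_index_series <- function(indices) {
  ggplot2::ggplot(indices,
                  ggplot2::aes(x = .data$month, y = .data$value,
                               size = .data$n_tokens)) +
    ggplot2::geom_point(alpha = 0.6, colour = "grey25") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_size_continuous(range = c(0.3, 2.5)) +
    ggplot2::labs(x = "age (months)", y = "value", size = "tokens") +
    ggplot2::theme_minimal()
}
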