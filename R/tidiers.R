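#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an rETR saturation fit
#'
#' @param x A `retr_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`),
#'   including the derived `E_K` and `phi_psii_50`.
#' @method tidy retr_fit
#' @export
tidy.retr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rETR_M", "alpha", "E_K", "phi_psii_50"),
    estimate = c(x$rETR_M, x$alpha, x$E_K, x$phi_psii_50)
  )
}

#' One-row summary of an rETR saturation fit
#'
#' @param x A `retr_fit` object.
#' @param ... Unused.
#' @method glance retr_fit
#' @export
glance.retr_fit <- function(x, ...) {
  tibble::tibble(rETR_M = x$rETR_M, alpha = x$alpha, E_K = x$E_K,
                 phi_psii_50 = x$phi_psii_50, rss = x$rss,
                 n = nrow(x$data), converged = x$converged)
}

#' Tidy an NPQ sigmoid fit
#'
#' @param x An `npq_fit` object.
#' @param ... Unused.
#' @method tidy npq_fit
#' @export
tidy.npq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("NPQ_M", "E50_NPQ", "n_sig"),
    estimate = c(x$NPQ_M, x$E50_NPQ, x$n_sig)
  )
}

#' One-row summary of an NPQ sigmoid fit
#'
#' @param x An `npq_fit` object.
#' @param ... Unused.
#' @method glance npq_fit
#' @export
glance.npq_fit <- function(x, ...) {
  tibble::tibble(NPQ_M = x$NPQ_M, E50_NPQ = x$E50_NPQ, n_sig = x$n_sig,
                 rss = x$rss, n = nrow(x$data), converged = x$converged)
}

#' Plot an rETR saturation fit
#'
#' Observed rETR against irradiance with the fitted saturation curve.
#'
#' @param object A `retr_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot retr_fit
#' @export
autoplot.retr_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$E, y = .data$retr)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(paste("E (", mu, "mol photons ", m^-2, " ", s^-1, ")")),
      y = "rETR"
    ) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(E = seq(0, max(object$data$E), length.out = 200))
    grid$retr <- retr_model(grid$E, object$rETR_M, object$alpha)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Plot an NPQ sigmoid fit
#'
#' @param object An `npq_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npq_fit
#' @export
autoplot.npq_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$E, y = .data$npq)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(paste("E (", mu, "mol photons ", m^-2, " ", s^-1, ")")),
      y = "NPQ"
    ) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(E = seq(0, max(object$data$E), length.out = 200))
    grid$npq <- npq_model(grid$E, object$NPQ_M, object$E50_NPQ, object$n_sig)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Plot a growth curve with the log-phase window
#'
#' Log10 cell density against time, with the density window used for rate
#' estimation shaded.
#'
#' @param curve Growth tibble (`time_days`, `cells_per_ml`).
#' @param lower,upper Density window bounds (defaults as in
#'   [log_phase_rate()]).
#' @return A ggplot.
#' @export
plot_growth_curve <- function(curve, lower = 5e4, upper = 4e6) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$time_days, y = .data$cells_per_ml)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = lower,
                      ymax = upper, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells / mL") +
    ggplot2::theme_minimal()
}

#' Plot normalised meta-gene abundance against absolute latitude
#'
#' @param normalized Tibble from [normalize_abundances()] joined to station
#'   metadata (needs `latitude` and the chosen response column).
#' @param response Column to plot (default `log_expression_ratio`).
#' @return A ggplot.
#' @export
plot_abundance_latitude <- function(normalized,
                                    response = "log_expression_ratio") {
  ggplot2::ggplot(normalized, ggplot2::aes(
    x = abs(.data$latitude), y = .data[[response]]
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "absolute latitude (degrees)", y = response) +
    ggplot2::theme_minimal()
}
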