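#' Plot developmental trajectories from a GAMM fit
#'
#' Fitted response-versus-age curve with a pointwise confidence band and
#' the observed sessions. For nT2*w responses the y-axis can be reversed
#' (`reverse_y = TRUE`) so that more tissue iron (lower nT2*w) is higher on
#' the axis — a display convention only; stored values are never
#' sign-flipped.
#'
#' @param fit A [fit_gamm()] result.
#' @param grid_n Age-grid size.
#' @param level Confidence level.
#' @param reverse_y Reverse the y-axis (tissue-iron display convention)?
#' @return A ggplot object.
#' @export
plot_trajectory <- function(fit, grid_n = 200, level = 0.95,
                            reverse_y = FALSE) {
  ages <- fit$data$age
  grid <- seq(min(ages), max(ages), length.out = grid_n)
  nd <- fit$data[rep(1L, grid_n), , drop = FALSE]
  nd$age <- grid
  for (v in fit$linear) {
    nd[[v]] <- if (is.numeric(fit$data[[v]])) mean(fit$data[[v]]) else
      fit$data[[v]][1]
  }
  excl <- if (!is.null(fit$random)) sprintf("s(%s)", fit$random) else NULL
  pr <- stats::predict(fit$gam, newdata = nd, se.fit = TRUE, exclude = excl)
  z <- stats::qnorm(1 - (1 - level) / 2)
  curve <- tibble::tibble(age = grid, estimate = as.numeric(pr$fit),
                          lo = pr$fit - z * pr$se.fit,
                          hi = pr$fit + z * pr$se.fit)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(
      data = fit$data,
      ggplot2::aes(y = .data[[fit$response]]), alpha = 0.3, size = 0.8) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), linewidth = 1) +
    ggplot2::labs(x = "Age (years)", y = fit$response)
  if (reverse_y) p <- p + ggplot2::scale_y_reverse()
  p
}

#' Plot a windows-of-significance result
#'
#' The monitored quantity (term or its derivative) across age with its
#' interval, shading the detected windows.
#'
#' @param object A `window_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_result <- function(object, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Age (years)",
                  y = if (object$mode == "derivative")
                    "First derivative" else "Coefficient",
                  title = object$term)
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf), alpha = 0.12)
  }
  p
}

#' Plot marginal trajectories at fixed behavior levels
#'
#' @param object A [marginal_trajectories()] tibble.
#' @param reverse_y Reverse the y-axis (tissue-iron display convention)?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marginal_trajectories <- function(object, reverse_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$age, y = .data$estimate,
    color = factor(.data$level_sd), group = .data$level_sd)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Age (years)", y = "Predicted response",
                  color = "Behavior (SD)")
  if (reverse_y) p <- p + ggplot2::scale_y_reverse()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
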