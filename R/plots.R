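# Diagnostic ggplot2 graphics for the package's result objects.

#' Plot spindle-versus-cell-volume scaling
#'
#' Scatter of spindle volume against cell volume coloured by state, with
#' per-bin medians overlaid when bin edges are given — the standard view of
#' the subscaling comparison.
#'
#' @param records per-cell tibble with `V_cell_um3`, `V_spindle_um3` and
#'   `state`.
#' @param edges optional bin edges for median overlays.
#' @return a ggplot object.
#' @export
plot_spindle_scaling <- function(records, edges = seq(1000, 3500, 500)) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(.data$V_cell_um3, .data$V_spindle_um3,
                                    colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = expression("Cell volume (" * mu * m^3 * ")"),
                  y = expression("Spindle volume (" * mu * m^3 * ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(edges)) {
    meds <- records %>%
      group_by(.data$state) %>%
      dplyr::group_modify(~ summarise_bins(.x, edges)) %>%
      ungroup() %>%
      mutate(center = (.data$bin_low + .data$bin_high) / 2)
    p <- p +
      ggplot2::geom_pointrange(
        data = meds,
        ggplot2::aes(x = .data$center, y = .data$median,
                     ymin = .data$iqr_low, ymax = .data$iqr_high,
                     colour = .data$state),
        inherit.aes = FALSE, size = 0.6)
  }
  p
}

#' @describeIn fit_recovery plot the normalized post-bleach data with the
#'   fitted exponential recovery curve.
#' @param object a `frap_fit`.
#' @param ... unused.
#' @export
autoplot.frap_fit <- function(object, ...) {
  grid <- tibble(time_s = seq(0, max(object$data$time_s), length.out = 200))
  grid$fit <- object$A * (1 - exp(-grid$time_s / object$tau)) + object$C
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$normalized)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(x = "Time after bleach (s)", y = "Normalized intensity",
                  subtitle = sprintf("t1/2 = %.2f s", object$t_half)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_saturation_curve plot binned counts, the fitted
#'   Michaelis-Menten curve and the predicted saturation plateau.
#' @param object a `saturation_fit`.
#' @param ... unused.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  grid <- tibble(v = seq(0, max(object$data$bin_center_um3) * 1.2,
                         length.out = 200))
  grid$fit <- object$N_sat * grid$v / (object$K_V + grid$v)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$bin_center_um3, .data$mean_count)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_count - .data$count_sd,
                   ymax = .data$mean_count + .data$count_sd)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$v, .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$N_sat, linetype = "dashed") +
    ggplot2::labs(x = expression("Cell volume (" * mu * m^3 * ")"),
                  y = "Astral microtubule count",
                  subtitle = sprintf("N_sat = %.1f, K_V = %.0f um^3",
                                     object$N_sat, object$K_V)) +
    ggplot2::theme_minimal()
}
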