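#' Plot a direction tuning curve
#'
#' Mean baseline-subtracted response versus stimulus direction with SEM
#' ribbons, in the field's convention (response at -180 replotted from 180
#' when present).
#'
#' @param curve A `tuning_curve`.
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(curve) {
  d <- tibble::as_tibble(curve)
  if (180 %in% d$direction && !(-180 %in% d$direction)) {
    rep_row <- d[d$direction == 180, ]
    rep_row$direction <- -180
    d <- rbind(rep_row, d)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direction, y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$response - .data$sem,
                   ymax = .data$response + .data$sem), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "airflow direction (deg)",
                  y = "response (spikes/s)") +
    ggplot2::theme_classic()
}

#' Scatter of similarity coefficients
#'
#' Plots rho_air against rho_stripe per cell; points on the diagonal
#' indicate summation-like integration, points off it dominance of one
#' modality.
#'
#' @param tbl Tibble with columns `rho_air`, `rho_stripe` (and optionally a
#'   grouping column mapped by `colour`).
#' @param colour Optional column name for point colour.
#' @return A ggplot object.
#' @export
plot_rho_scatter <- function(tbl, colour = NULL) {
  aes <- if (is.null(colour))
    ggplot2::aes(x = .data$rho_air, y = .data$rho_stripe)
  else
    ggplot2::aes(x = .data$rho_air, y = .data$rho_stripe,
                 colour = .data[[colour]])
  ggplot2::ggplot(tbl, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = expression(rho[a] ~ "(airflow)"),
                  y = expression(rho[s] ~ "(stripe)")) +
    ggplot2::theme_classic()
}

#' Stick-and-ball plot of per-fly fixation
#'
#' Each fly is a stick from the origin at its mean orientation, with length
#' equal to its fixation strength (dashed circle at 0.5); the airflow
#' source is at 0 degrees (up).
#'
#' @param tbl Tibble with columns `mean_orientation` (deg) and `strength`,
#'   one row per fly (optional `genotype` column for colour).
#' @return A ggplot object.
#' @export
plot_fixation_sticks <- function(tbl) {
  th <- deg2rad(90 - tbl$mean_orientation)   # 0 deg points up
  d <- dplyr::mutate(tbl, x = .data$strength * cos(th),
                     y = .data$strength * sin(th))
  circ <- tibble::tibble(a = seq(0, 2 * pi, length.out = 181))
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_path(data = dplyr::mutate(circ, x = 0.5 * cos(.data$a),
                                            y = 0.5 * sin(.data$a)),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = "dashed", colour = "grey60")
  seg_aes <- if ("genotype" %in% names(d))
    ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y,
                 colour = .data$genotype)
  else ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y)
  p + ggplot2::geom_segment(data = d, seg_aes) +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("text", x = 0, y = 1.08, label = "airflow (0 deg)") +
    ggplot2::coord_equal(xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.15)) +
    ggplot2::theme_void()
}

#' Mean perturbation-triggered dWBA timecourses
#'
#' @param pr A `perturbation_response` from [slip_responses()] or
#'   [pause_responses()].
#' @return A ggplot object (mean +/- SEM per perturbation type).
#' @export
plot_perturbation_timecourses <- function(pr) {
  ggplot2::ggplot(pr$timecourses,
                  ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = "time from perturbation onset (s)",
                  y = "dWBA (deg)") +
    ggplot2::theme_classic()
}
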