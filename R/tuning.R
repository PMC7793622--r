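#' Build a direction tuning curve from per-trial responses
#'
#' Per-direction mean baseline-subtracted responses with trial counts and
#' SEM. Responses may be negative (inhibition).
#'
#' @param direction Direction label per trial, degrees.
#' @param response Baseline-subtracted response per trial.
#' @return A `tuning_curve` tibble: `direction`, `response` (mean), `sem`,
#'   `n`, sorted by direction.
#' @export
tuning_curve <- function(direction, response) {
  stopifnot(length(direction) == length(response))
  tc <- tibble::tibble(direction = direction, response = response) |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      sem = sd(.data$response) / sqrt(dplyr::n()),
      n = dplyr::n(),
      response = mean(.data$response),
      .groups = "drop") |>
    dplyr::select("direction", "response", "sem", "n") |>
    dplyr::arrange(.data$direction)
  if (nrow(tc) < 2) stop("a tuning curve needs at least 2 directions")
  class(tc) <- c("tuning_curve", class(tc))
  tc
}

#' Mean response vector of a tuning curve
#'
#' Converts each per-direction mean response into a vector with angle equal
#' to the stimulus direction and magnitude equal to the mean response, and
#' returns the resultant. Responses are kept signed by default: a negative
#' (inhibitory) response pulls the resultant away from its direction. The
#' resultant length is normalized by the sum of absolute responses, so it
#' lies in [0, 1], reaching 1 when a single direction carries all the
#' (excitatory) response.
#'
#' @param curve A `tuning_curve`, or anything with `direction` and
#'   `response` columns.
#' @param rectify If `TRUE`, negative responses are clipped to zero before
#'   the resultant is computed (non-default variant).
#' @return A `vector_tuning` list: `angle` (degrees, `NA` with
#'   `undefined = TRUE` when the normalizer or resultant is null), `length`
#'   in [0, 1], `undefined`.
#' @export
mean_vector <- function(curve, rectify = FALSE) {
  r <- curve$response
  if (rectify) r <- pmax(r, 0)
  norm <- sum(abs(r))
  if (norm == 0)
    return(structure(list(angle = NA_real_, length = 0, undefined = TRUE),
                     class = "vector_tuning"))
  cm <- circ_mean(curve$direction, w = r)
  structure(
    list(angle = cm$angle, length = cm$length / norm,
         undefined = is.na(cm$angle)),
    class = "vector_tuning")
}

#' Cumulative response dynamics and time to half-max
#'
#' Characterizes response transience: the cumulative sum of the PSTH over
#' the 4 s stimulus period, normalized by its integral over that period, and
#' the time (relative to stimulus onset) at which the normalized cumulative
#' response first crosses 0.5 (linear interpolation between samples).
#' Transient responses reach 0.5 early; sustained responses near the 2 s
#' midpoint.
#'
#' @param x A `rate_series` from [psth()], or a numeric rate vector with
#'   `time`.
#' @param time Sample times when `x` is a bare vector, seconds.
#' @param window Stimulus window `c(onset, offset)`, seconds.
#' @return A `dynamics_profile`: `time` (s from stimulus onset),
#'   `cumulative` (normalized), `t_half` (s in [0, window length]),
#'   `undefined` (`TRUE`, with `t_half = NA`, when the PSTH integral over
#'   the window is not positive — possible for inhibited cells).
#' @export
dynamics <- function(x, time = NULL, window = c(4, 8)) {
  if (inherits(x, "rate_series")) {
    time <- x$time
    x <- x$rate
  }
  stopifnot(length(x) == length(time), diff(window) > 0)
  dt <- diff(time)[1]
  # half-sample slack: midpoint grids are valid supports for their bins
  if (window[1] < min(time) - dt / 2 - 1e-9 ||
      window[2] > max(time) + dt / 2 + 1e-9)
    stop("stimulus window outside PSTH support")
  sel <- time >= window[1] & time <= window[2]
  t <- time[sel] - window[1]
  total <- sum(x[sel]) * dt
  if (!is.finite(total) || total <= 0)
    return(structure(list(time = t, cumulative = rep(NA_real_, sum(sel)),
                          t_half = NA_real_, undefined = TRUE),
                     class = "dynamics_profile"))
  cum <- cumsum(x[sel]) * dt / total
  i <- which(cum >= 0.5)[1]
  t_half <- if (i == 1) t[1] else {
    t[i - 1] + (0.5 - cum[i - 1]) / (cum[i] - cum[i - 1]) * (t[i] - t[i - 1])
  }
  structure(
    list(time = t, cumulative = cum, t_half = t_half, undefined = FALSE),
    class = "dynamics_profile")
}
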