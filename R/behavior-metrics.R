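#' Orientation fixation metrics
#'
#' Converts each orientation sample into a unit vector and summarizes the
#' distribution: the mean orientation (angle of the resultant), the fixation
#' strength (resultant length; 1 = perfect fixation, 0 = no preferred
#' orientation, inversely related to circular variance), and the fraction of
#' samples in the toward-the-airflow quadrant, the half-open interval
#' [-45, +45) degrees around the source.
#'
#' @param orientation A `behavior_record` or numeric orientation series
#'   (degrees).
#' @return A `fixation_metrics` list: `mean_orientation` (degrees),
#'   `strength` in [0, 1], `toward_fraction` in [0, 1], `n`.
#' @export
fixation_metrics <- function(orientation) {
  if (inherits(orientation, "behavior_record"))
    orientation <- orientation$data$orientation
  stopifnot(length(orientation) >= 1)
  cm <- circ_mean(orientation)
  structure(
    list(mean_orientation = cm$angle,
         strength = cm$length / length(orientation),
         toward_fraction = mean(orientation >= -45 & orientation < 45),
         n = length(orientation)),
    class = "fixation_metrics")
}

# Extract the 6 s analysis window (1 s pre to 5 s post perturbation onset)
# around each scheduled perturbation of the given kinds. Truncated windows
# are dropped and counted.
perturbation_windows <- function(record, kinds) {
  fs <- record$arena$fs
  d <- record$data
  sched <- record$schedule[record$schedule$kind %in% kinds, ]
  pre <- round(1 * fs)
  post <- round(5 * fs)
  dropped <- 0L
  rows <- list()
  for (r in seq_len(nrow(sched))) {
    i0 <- round(sched$onset[r] * fs) + 1L     # first perturbed sample
    idx <- (i0 - pre):(i0 + post)
    if (idx[1] < 1L || idx[length(idx)] > nrow(d)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      trial = sched$trial[r], type = sched$type[r], onset = sched$onset[r],
      sign = sched$sign[r], n_samples = sched$n_samples[r],
      duration_s = sched$duration_s[r],
      time = (idx - i0) / fs,
      dwba = d$dwba[idx],
      orientation = d$orientation[idx])
  }
  if (dropped > 0)
    message(dropped, " truncated perturbation window(s) dropped")
  list(windows = dplyr::bind_rows(rows), dropped = dropped)
}

summarise_timecourses <- function(win) {
  win |>
    dplyr::group_by(.data$type, .data$time) |>
    dplyr::summarise(
      mean = mean(.data$dwba),
      sem = sd(.data$dwba) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
}

#' Slip-triggered dWBA responses
#'
#' For every slip trial, extracts dWBA in the 6 s window around onset (1 s
#' pre, 5 s post; 301 samples at 50 Hz), averages timecourses within each
#' slip type, and integrates dWBA over the 5 s following onset to obtain a
#' per-trial angular response (degree-seconds; positive = rightward).
#' Corrective responses have sign opposite the slip.
#'
#' @param record A `behavior_record`.
#' @return A `perturbation_response` list: `timecourses` tibble (`type`,
#'   `time`, `mean`, `sem`, `n`), `integrated` tibble (`trial`, `type`,
#'   `sign`, `slip_deg`, `integrated`), `dropped` count of truncated
#'   windows.
#' @export
slip_responses <- function(record) {
  fs <- record$arena$fs
  pw <- perturbation_windows(record, "slip")
  win <- pw$windows
  if (nrow(win) == 0) stop("no complete slip windows in record")
  integrated <- win |>
    dplyr::filter(.data$time > 0) |>
    dplyr::group_by(.data$trial, .data$type, .data$sign,
                    .data$n_samples) |>
    dplyr::summarise(integrated = sum(.data$dwba) / fs, .groups = "drop") |>
    dplyr::mutate(
      slip_deg = apply_slip_vec(.data$n_samples, .data$sign,
                                record$arena)) |>
    dplyr::select("trial", "type", "sign", "slip_deg", "integrated")
  structure(
    list(timecourses = summarise_timecourses(win), integrated = integrated,
         dropped = pw$dropped),
    class = "perturbation_response")
}

apply_slip_vec <- function(n_samples, sign, arena) {
  sign * arena$motor_max * n_samples / arena$fs
}

#' Fraction of a slip corrected by the fly
#'
#' Each trial's integrated slip response is converted into the equivalent
#' virtual-orientation change through the closed-loop mapping (multiplied
#' by `gain * fs`, since each sample contributes `gain * dwba` degrees) and
#' divided by the negative signed slip displacement; the mean over trials
#' is returned. A value of 1 means the fly's turning exactly undid the
#' imposed displacement, 0 means no response, negative values are
#' anti-corrective.
#'
#' @param integrated Integrated dWBA responses, degree-seconds (one per
#'   trial).
#' @param slip_deg Signed slip displacement per trial, degrees (non-zero).
#' @param arena The [arena_config()] used (for the dWBA-to-orientation
#'   conversion).
#' @param convert If `FALSE`, divide the raw dWBA integral by the slip
#'   magnitude without unit conversion (the mixed-units variant).
#' @return Mean correction fraction (dimensionless).
#' @export
correction_fraction <- function(integrated, slip_deg,
                                arena = arena_config(), convert = TRUE) {
  stopifnot(length(integrated) == length(slip_deg), all(slip_deg != 0))
  equiv <- if (convert) integrated * arena$gain * arena$fs else integrated
  mean(equiv / (-slip_deg))
}

#' Per-magnitude correction fractions for a session
#'
#' Convenience wrapper: runs [slip_responses()] and returns the correction
#' fraction for long and short slips (left and right pooled through the
#' signed division).
#'
#' @param record A `behavior_record`.
#' @inheritParams correction_fraction
#' @return Tibble: `magnitude` ("long", "short"), `correction_fraction`,
#'   `n_trials`.
#' @export
correction_fractions <- function(record, convert = TRUE) {
  ir <- slip_responses(record)$integrated
  ir$magnitude <- ifelse(ir$type %in% c("slip_right_long", "slip_left_long"),
                         "long", "short")
  ir |>
    dplyr::group_by(.data$magnitude) |>
    dplyr::summarise(
      correction_fraction = correction_fraction(
        .data$integrated, .data$slip_deg, record$arena, convert),
      n_trials = dplyr::n(), .groups = "drop")
}

#' Pause-triggered dWBA responses (toward/away sign convention)
#'
#' Airflow-pause responses are made direction-invariant by flipping the
#' sign of dWBA on each sample so that turns toward the airflow source are
#' positive and turns away are negative (the source is toward decreasing
#' |orientation|). Timecourses are averaged per pause type, and for long
#' pauses the sign-adjusted dWBA is additionally integrated over the 2 s
#' stimulus period.
#'
#' @param record A `behavior_record`.
#' @return A `perturbation_response` list: `timecourses` (sign-adjusted),
#'   `integrated` (long-pause 2 s integrals, degree-seconds, positive =
#'   toward), `dropped`.
#' @export
pause_responses <- function(record) {
  fs <- record$arena$fs
  pw <- perturbation_windows(record, "pause")
  win <- pw$windows
  if (nrow(win) == 0) stop("no complete pause windows in record")
  win$dwba <- win$dwba * toward_sign(win$orientation)
  integrated <- win |>
    dplyr::filter(.data$type == "pause_long", .data$time > 0,
                  .data$time <= .data$duration_s) |>
    dplyr::group_by(.data$trial, .data$type) |>
    dplyr::summarise(integrated = sum(.data$dwba) / fs, .groups = "drop")
  structure(
    list(timecourses = summarise_timecourses(win), integrated = integrated,
         dropped = pw$dropped),
    class = "perturbation_response")
}

#' Binned distribution of slip-response magnitudes
#'
#' Places integrated slip responses into fixed-width bins (20 degrees by
#' default), optionally collapsing across slip direction by sign-flipping
#' the responses to leftward slips, and normalizes counts to probabilities.
#' Bins are centered on multiples of the width.
#'
#' @param values Integrated responses (degrees or degree-seconds).
#' @param slip_sign Optional signed slip direction per value; when given,
#'   values from leftward (negative) slips are flipped before pooling.
#' @param bin_width Bin width, same units as `values` (> 0).
#' @return Tibble: `mid` (bin center), `count`, `prob` (sums to 1).
#' @export
response_histogram <- function(values, slip_sign = NULL, bin_width = 20) {
  stopifnot(bin_width > 0)
  if (!is.null(slip_sign)) {
    stopifnot(length(slip_sign) == length(values))
    values <- values * sign(slip_sign)
  }
  # value v falls in the bin centered on bin_width * floor((v + w/2) / w)
  c0 <- floor((min(values) + bin_width / 2) / bin_width)
  c1 <- floor((max(values) + bin_width / 2) / bin_width)
  breaks <- (seq(c0, c1 + 1L) - 0.5) * bin_width
  h <- hist(values, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts,
                 prob = h$counts / length(values))
}
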