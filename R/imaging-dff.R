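#' Motion-corrected delta-F/F from a two-channel series
#'
#' Computes per-channel dF/F against the mean fluorescence of the baseline
#' period (the first 5 s of the trial) and the ratiometric correction:
#' corrected dF/F = dF/F(green) - dF/F(red). Because motion artifacts
#' multiply both channels alike, the subtraction cancels them to within the
#' noise floor.
#'
#' @param series A `two_channel_series`, or a list/data frame with `time`,
#'   `green`, `red`.
#' @param baseline_window Baseline window, seconds.
#' @return A `dff_trace`: `time`, `green`, `red` (per-channel dF/F) and
#'   `corrected`.
#' @export
dff <- function(series, baseline_window = c(0, 5)) {
  t <- series$time
  stopifnot(baseline_window[1] >= min(t), baseline_window[2] <= max(t) + 1e-9)
  base <- t >= baseline_window[1] & t < baseline_window[2]
  one <- function(f) {
    f0 <- mean(f[base])
    if (f0 <= 0) stop("non-positive baseline mean fluorescence")
    (f - f0) / f0
  }
  g <- one(series$green)
  r <- one(series$red)
  structure(
    list(time = t, green = g, red = r, corrected = g - r,
         epochs = series$epochs, direction = series$direction),
    class = "dff_trace")
}

#' Per-epoch mean corrected dF/F
#'
#' Averages the corrected dF/F within each trial epoch (pre, airflow,
#' airflow+odor, airflow, post).
#'
#' @param x A `dff_trace`.
#' @param epochs Epoch table (`epoch`, `start`, `end`); defaults to the
#'   trace's stored epochs or [imaging_epochs()].
#' @return Tibble: `epoch`, `start`, `end`, `mean_dff`.
#' @export
epoch_summary <- function(x, epochs = NULL) {
  if (is.null(epochs)) epochs <- x$epochs
  if (is.null(epochs)) epochs <- imaging_epochs()
  if (min(epochs$start) < min(x$time) - 1e-9 ||
      max(epochs$end) > max(x$time) + 1 / 5 + 1e-9)
    stop("epoch boundaries outside trace")
  means <- vapply(seq_len(nrow(epochs)), function(i) {
    sel <- x$time >= epochs$start[i] & x$time < epochs$end[i]
    mean(x$corrected[sel])
  }, numeric(1))
  dplyr::mutate(epochs, mean_dff = means)
}
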