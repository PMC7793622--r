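#' Detect spikes by threshold crossings of the high-passed voltage
#'
#' The raw membrane potential is high-pass filtered with a second-order
#' Butterworth filter (40 Hz cutoff by default), applied forward-backward so
#' spike times are not shifted, and spikes are counted as upward crossings of
#' a threshold — one spike per suprathreshold excursion (rising edge). The
#' threshold is cell-specific; by default it self-scales as a multiple of the
#' median absolute deviation of the filtered trace.
#'
#' @param trace A `voltage_trace`, or a numeric vector (then supply `fs`).
#' @param threshold Absolute threshold in mV on the filtered trace, or `NULL`
#'   to use `mad_mult` * MAD.
#' @param mad_mult Multiplier for the MAD-based default threshold.
#' @param cutoff High-pass cutoff frequency, Hz (must be < fs/2).
#' @param fs Sampling rate when `trace` is a bare numeric vector.
#' @return A `spike_train`: sorted spike times in seconds, with the threshold
#'   used stored as attribute `threshold`.
#' @export
detect_spikes <- function(trace, threshold = NULL, mad_mult = 5,
                          cutoff = 40, fs = NULL) {
  if (inherits(trace, "voltage_trace")) {
    v <- trace$samples
    fs <- trace$fs
  } else {
    v <- as.numeric(trace)
    if (is.null(fs)) stop("supply `fs` for a bare numeric trace")
  }
  stopifnot(cutoff > 0, cutoff < fs / 2)
  hp <- signal::butter(2, cutoff / (fs / 2), type = "high")
  f <- signal::filtfilt(hp, v)
  if (is.null(threshold)) threshold <- mad_mult * mad(f)
  if (!is.finite(threshold)) stop("spike threshold must be finite")
  above <- f >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  structure((rising - 1) / fs, class = "spike_train", threshold = threshold)
}

# Unit-area Hanning kernel of the given width in seconds, sampled at 1/dt.
hanning_kernel <- function(width, dt) {
  n <- max(3L, round(width / dt))
  if (n %% 2 == 0) n <- n + 1L             # odd length: centered kernel
  k <- as.numeric(signal::hanning(n))
  k / (sum(k) * dt)
}

#' Peristimulus time histogram by Hanning-kernel smoothing
#'
#' Each spike train is binned on a regular grid and convolved with a
#' unit-area 1 s Hanning window, then trains are averaged. The returned
#' series extends half a kernel width beyond `t_range` on each side so that
#' no smoothed mass is truncated: because the kernel has unit area, the PSTH
#' integrates (to numerical tolerance) to the mean spike count per trial.
#'
#' @param spike_trains A list of spike-time vectors (seconds), or one vector.
#' @param kernel_width Hanning window width, seconds.
#' @param t_range Trial time support `c(start, end)`, seconds; all spikes
#'   must lie within it.
#' @param fs_out Output sampling rate of the rate series, Hz.
#' @return A `rate_series` list: `time` (s, extending `kernel_width / 2`
#'   past each end of `t_range`), `rate` (spikes/s, the mean over trials),
#'   `n_trials`, `kernel_width`, `t_range`.
#' @export
psth <- function(spike_trains, kernel_width = 1, t_range = c(0, 12),
                 fs_out = 1000) {
  if (is.numeric(spike_trains)) spike_trains <- list(spike_trains)
  if (length(spike_trains) == 0) stop("no spike trains supplied")
  stopifnot(kernel_width > 0)
  dt <- 1 / fs_out
  edges <- seq(t_range[1], t_range[2], by = dt)
  mids <- edges[-length(edges)] + dt / 2
  k <- hanning_kernel(kernel_width, dt)
  half <- (length(k) - 1L) / 2L
  rates <- vapply(spike_trains, function(st) {
    counts <- if (length(st)) {
      tabulate(findInterval(st, edges, rightmost.closed = TRUE),
               nbins = length(mids))
    } else numeric(length(mids))
    stats::convolve(counts, rev(k), type = "open")
  }, numeric(length(mids) + 2L * half))
  time_ext <- mids[1] + (seq_len(length(mids) + 2L * half) - 1L - half) * dt
  structure(
    list(time = time_ext, rate = rowMeans(rates),
         n_trials = length(spike_trains), kernel_width = kernel_width,
         t_range = t_range),
    class = "rate_series")
}

#' Windowed baseline-subtracted stimulus response
#'
#' Mean of the series in the response window minus its mean in the baseline
#' window. The default windows are 1 s segments ending 500 ms before, and
#' starting 500 ms after, stimulus onset. Works on a firing-rate series
#' (spikes/s) or on membrane potential (mV).
#'
#' @param x Numeric series (rate or Vm) or a `rate_series`.
#' @param time Sample times (seconds); taken from `x` if it is a
#'   `rate_series`.
#' @param stim_onset Stimulus onset, seconds (used for default windows).
#' @param baseline,response Two-element window vectors `c(start, end)`.
#' @return Scalar response (same units as `x`).
#' @export
trial_response <- function(x, time = NULL, stim_onset = 4,
                           baseline = c(stim_onset - 1.5, stim_onset - 0.5),
                           response = c(stim_onset + 0.5, stim_onset + 1.5)) {
  if (inherits(x, "rate_series")) {
    time <- x$time
    x <- x$rate
  }
  stopifnot(length(x) == length(time))
  tr <- range(time)
  if (baseline[1] < tr[1] || response[2] > tr[2])
    stop("analysis windows fall outside the trace")
  win_mean <- function(w) mean(x[time >= w[1] & time < w[2]])
  win_mean(response) - win_mean(baseline)
}

#' Input resistance from the test pulse
#'
#' Measures the steady-state voltage deflection produced by the small
#' hyperpolarizing test pulse at the start of each trial and divides by the
#' injected current. The steady state is the mean over the second half of the
#' pulse; the reference level is a same-length window after the pulse ends
#' (plus a settle margin), since the pulse begins at trial onset.
#'
#' @param trace A `voltage_trace`, or numeric vector with `fs`.
#' @param pulse Pulse spec (`onset`, `duration`, `current` in pA); defaults
#'   to the trace's trial pulse.
#' @param settle Settling time after pulse offset before the reference
#'   window, seconds.
#' @param fs Sampling rate for bare numeric traces.
#' @return Input resistance in GOhm (mV / pA).
#' @export
input_resistance <- function(trace, pulse = NULL, settle = 0.1, fs = NULL) {
  if (inherits(trace, "voltage_trace")) {
    v <- trace$samples
    fs <- trace$fs
    if (is.null(pulse)) pulse <- trace$trial$pulse
  } else {
    v <- as.numeric(trace)
    if (is.null(fs) || is.null(pulse)) stop("supply `fs` and `pulse`")
  }
  if (pulse$current == 0) stop("test-pulse current is zero")
  t <- (seq_along(v) - 1) / fs
  off <- pulse$onset + pulse$duration
  half <- pulse$duration / 2
  if (off + settle + half > max(t)) stop("pulse epoch outside trace")
  ss <- mean(v[t >= off - half & t < off])
  ref <- mean(v[t >= off + settle & t < off + settle + half])
  (ss - ref) / pulse$current
}

# Welch power spectral density: Hann-windowed overlapping segments.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  norm <- fs * sum(w^2)
  p <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    (Mod(fft(seg))^2 / norm)[1:(seg_len %/% 2 + 1L)]
  }, numeric(seg_len %/% 2 + 1L)))
  list(freq = (0:(seg_len %/% 2)) * fs / seg_len, power = p)
}

#' Baseline-state profile of a recording
#'
#' Summarizes the baseline (pre-stimulus) membrane potential: resting
#' potential as the mode of the Vm distribution, distribution width as the
#' 5th-95th percentile range (rhythmic neurons have broader distributions),
#' oscillation frequency as the dominant Welch-periodogram peak in a low
#' band (none if the peak is not prominent), and input resistance from the
#' test pulse.
#'
#' @param traces A `voltage_trace` or list of them (same neuron).
#' @param band Frequency band searched for an oscillation, Hz (the
#'   observed oscillations sit at 2-4 Hz; the post-pulse baseline segment
#'   must span two periods of the low edge).
#' @param prominence Peak must exceed `prominence` times the median spectral
#'   power in the band to count as an oscillation.
#' @return A `baseline_profile` list: `v_rest` (mV), `width` (mV),
#'   `osc_freq` (Hz or `NA`), `r_in` (GOhm).
#' @export
baseline_profile <- function(traces, band = c(1, 10), prominence = 4) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  fs <- traces[[1]]$fs
  # baseline Vm after the pulse has settled, before stimulus onset
  segs <- lapply(traces, function(tr) {
    t <- trace_time(tr)
    p <- tr$trial$pulse
    tr$samples[t >= p$onset + p$duration + 0.25 & t < tr$trial$stim_onset]
  })
  vm <- unlist(segs)
  if (length(segs[[1]]) < 2 * fs / band[1])
    stop("baseline segment shorter than two periods at the low band edge")
  d <- density(vm)
  q <- quantile(vm, c(0.05, 0.95), names = FALSE)
  # average Welch spectra across trials; decimate to keep FFTs small
  dec <- max(1L, floor(fs / 500))
  fs_d <- fs / dec
  spectra <- lapply(segs, function(s) {
    welch_psd(s[seq(1L, length(s), by = dec)], fs_d,
              seg_len = round(2 * fs_d))
  })
  pw <- rowMeans(vapply(spectra, `[[`, numeric(length(spectra[[1]]$power)),
                        "power"))
  fr <- spectra[[1]]$freq
  in_band <- fr >= band[1] & fr <= band[2]
  pk <- which.max(pw[in_band])
  osc <- if (pw[in_band][pk] >= prominence * median(pw[in_band]))
    fr[in_band][pk] else NA_real_
  r_in <- mean(vapply(traces, input_resistance, numeric(1)))
  structure(
    list(v_rest = d$x[which.max(d$y)], width = diff(q), osc_freq = osc,
         r_in = r_in),
    class = "baseline_profile")
}

#' Strongest-direction response of a cell
#'
#' Averages signed per-trial responses within each direction, selects the
#' direction whose mean response has the largest absolute value, and returns
#' that absolute mean (inhibition can win).
#'
#' @param direction Direction label per trial, degrees.
#' @param response Baseline-subtracted response per trial (spikes/s or mV).
#' @return List: `direction` (degrees) and `response` (non-negative mean
#'   absolute response at that direction). All-zero input returns the first
#'   direction by convention.
#' @export
strongest_direction_response <- function(direction, response) {
  stopifnot(length(direction) == length(response), length(response) >= 1)
  m <- tapply(response, direction, mean)
  i <- which.max(abs(m))
  list(direction = as.numeric(names(m)[i]), response = abs(unname(m[i])))
}

#' Per-trial response table for a simulated or recorded session
#'
#' Runs spike detection, PSTH-free windowed spike-rate responses (counts in
#' the two 1 s windows) and membrane-potential responses for every trace,
#' returning the tidy per-trial table the downstream tuning and integration
#' stages consume.
#'
#' @param traces List of `voltage_trace` objects.
#' @param ... Passed to [detect_spikes()].
#' @return Tibble: fly, cell, trial, direction, condition, response
#'   (spikes/s), vm_response (mV), n_spikes.
#' @export
session_responses <- function(traces, ...) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    st <- detect_spikes(tr, ...)
    on <- tr$trial$stim_onset
    base_w <- c(on - 1.5, on - 0.5)
    resp_w <- c(on + 0.5, on + 1.5)
    rate_in <- function(w) sum(st >= w[1] & st < w[2]) / diff(w)
    tibble::tibble(
      fly = tr$fly_id, cell = tr$neuron_id, trial = i,
      direction = tr$trial$direction, condition = tr$trial$condition,
      response = rate_in(resp_w) - rate_in(base_w),
      vm_response = trial_response(tr$samples, trace_time(tr),
                                   stim_onset = on),
      n_spikes = length(st))
  })
  dplyr::bind_rows(rows)
}
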