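#' Imaging trial epoch structure
#'
#' The two-photon trial design: 5 s pre-stimulus, 10 s airflow, 10 s
#' airflow plus odor, another 10 s airflow, and 12 s post-stimulus, imaged
#' at 5.0 frames per second.
#'
#' @return Tibble: `epoch`, `start`, `end` (seconds).
#' @export
imaging_epochs <- function() {
  tibble::tibble(
    epoch = c("pre", "airflow_1", "airflow_odor", "airflow_2", "post"),
    start = c(0, 5, 15, 25, 35),
    end = c(5, 15, 25, 35, 47))
}

#' Parameterize an imaged ROI
#'
#' Generative model for one region of interest recorded in two channels: an
#' activity indicator (green) whose fluorescence is modulated by a
#' direction-tuned airflow response with calcium-like kinetics, and a
#' structural indicator (red) that shares the slow motion artifact but
#' carries no response. The tuning family is the same circular Gaussian
#' used by the electrophysiology generator; `sign_invert` flips the
#' response sign (these lateral-accessory-lobe inputs are tuned
#' sign-inverted with respect to their downstream columnar partners). Odor
#' leaves the response unchanged by default (`odor_gain = 1`).
#'
#' @param baseline_green,baseline_red Baseline fluorescence, a.u. (> 0).
#' @param amp Peak fractional response (dF/F) at the preferred direction.
#' @param pref_dir,tuning_width,inhib Tuning parameters, see
#'   [tuning_shape()].
#' @param sign_invert Flip the response sign.
#' @param odor_gain Multiplicative response modulation during the odor
#'   epoch.
#' @param noise_sd Additive per-frame noise SD, a.u.
#' @param tau_on,tau_off Indicator rise and decay time constants, s.
#' @return An `roi_model` list.
#' @export
roi_model <- function(baseline_green = 100, baseline_red = 100, amp = 0.5,
                      pref_dir = 90, tuning_width = 60, inhib = 0,
                      sign_invert = FALSE, odor_gain = 1, noise_sd = 1,
                      tau_on = 0.5, tau_off = 2) {
  if (baseline_green <= 0 || baseline_red <= 0)
    stop("channel baselines must be positive")
  stopifnot(noise_sd >= 0, tau_on > 0, tau_off > 0, odor_gain > 0)
  structure(
    list(baseline_green = baseline_green, baseline_red = baseline_red,
         amp = amp, pref_dir = pref_dir, tuning_width = tuning_width,
         inhib = inhib, sign_invert = sign_invert, odor_gain = odor_gain,
         noise_sd = noise_sd, tau_on = tau_on, tau_off = tau_off),
    class = "roi_model")
}

# Gaussian smoothing with replicated-edge padding.
smooth_gauss <- function(x, sd_samples) {
  half <- max(1L, ceiling(4 * sd_samples))
  k <- exp(-0.5 * (seq(-half, half) / sd_samples)^2)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Simulate a two-channel ROI fluorescence trial
#'
#' Green channel: baseline x (1 + tuned response) x artifact + noise.
#' Red channel: baseline x artifact + noise. The artifact is a smooth,
#' low-frequency multiplicative process shared by both channels (emulating
#' fluctuations in the imaging plane from brain movement), so
#' channel-subtracted dF/F cancels it while single-channel dF/F does not.
#'
#' @param roi An [roi_model()].
#' @param direction Airflow direction, degrees.
#' @param artifact_amp SD of the multiplicative artifact about 1 (>= 0).
#' @param seed Integer seed.
#' @param fs Frame rate, Hz.
#' @return A `two_channel_series`: `time`, `green`, `red`, `direction`,
#'   `fs`, `epochs`, `seed`, and the ground-truth `response` fraction.
#' @export
simulate_two_channel <- function(roi, direction, artifact_amp = 0.1, seed = 1,
                                 fs = 5) {
  stopifnot(artifact_amp >= 0, fs > 0)
  ep <- imaging_epochs()
  t_end <- max(ep$end)
  n <- round(t_end * fs)
  t <- (seq_len(n) - 1) / fs
  resp <- roi_response(roi, direction, t)
  out <- withr::with_seed(seed, {
    art <- if (artifact_amp > 0) {
      s <- smooth_gauss(rnorm(n), sd_samples = 2 * fs)
      1 + artifact_amp * (s - mean(s)) / sd(s)
    } else rep(1, n)
    list(art = pmax(art, 0.05),
         ng = rnorm(n, 0, roi$noise_sd), nr = rnorm(n, 0, roi$noise_sd))
  })
  structure(
    list(time = t,
         green = roi$baseline_green * (1 + resp) * out$art + out$ng,
         red = roi$baseline_red * out$art + out$nr,
         direction = direction, fs = fs, epochs = ep, seed = seed,
         response = resp),
    class = "two_channel_series")
}

# Tuned fractional response timecourse: drive during the 30 s airflow block
# (odor-gain modulated in the middle epoch), filtered through first-order
# rise/decay kinetics.
roi_response <- function(roi, direction, t) {
  ep <- imaging_epochs()
  on <- ep$start[ep$epoch == "airflow_1"]
  off <- ep$end[ep$epoch == "airflow_2"]
  odor <- t >= ep$start[ep$epoch == "airflow_odor"] &
    t < ep$end[ep$epoch == "airflow_odor"]
  drive <- as.numeric(t >= on & t < off)
  drive[odor] <- drive[odor] * roi$odor_gain
  amp <- roi$amp * tuning_shape(direction, roi$pref_dir, roi$tuning_width,
                                roi$inhib)
  if (roi$sign_invert) amp <- -amp
  dt <- diff(t)[1]
  env <- numeric(length(t))
  level <- 0
  for (i in seq_along(t)) {
    tau <- if (drive[i] >= level) roi$tau_on else roi$tau_off
    level <- level + (drive[i] - level) * (1 - exp(-dt / tau))
    env[i] <- level
  }
  amp * env
}
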