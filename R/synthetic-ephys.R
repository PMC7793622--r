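#' Stimulus conditions used in the columnar-neuron survey
#'
#' The five cue combinations presented in the survey sessions: a high-contrast
#' vertical stripe, an airflow stream, both together, odorized airflow, and all
#' three modalities at once.
#'
#' @export
survey_conditions <- function() {
  c("stripe", "airflow", "stripe+airflow", "airflow+odor",
    "stripe+airflow+odor")
}

#' The four survey stimulus directions
#'
#' Front (0), rear (180), ipsilateral (+90) and contralateral (-90) to the
#' recorded neuron, in the fixed order used when concatenating per-direction
#' response timecourses.
#'
#' @export
survey_directions <- function() c(-90, 0, 90, 180)

#' Specify a single 12 s recording trial
#'
#' Each trial has 4 s of pre-stimulus baseline, 4 s of stimulus presentation
#' and 4 s of post-stimulus time. The first second of baseline carries a
#' 500 ms, -2 pA current injection used to track input resistance.
#'
#' @param direction Stimulus direction in degrees on (-180, 180].
#' @param condition One of [survey_conditions()].
#' @param t_baseline,t_stim,t_post Segment durations in seconds.
#' @param pulse List with `onset` (s), `duration` (s) and `current` (pA) of
#'   the test pulse; must lie entirely within the first second of baseline.
#' @return A `trial_spec` list with the segment boundaries precomputed
#'   (`stim_onset`, `stim_offset`, `duration`).
#' @export
trial_spec <- function(direction, condition,
                       t_baseline = 4, t_stim = 4, t_post = 4,
                       pulse = list(onset = 0, duration = 0.5, current = -2)) {
  condition <- match.arg(condition, survey_conditions())
  stopifnot(
    is.numeric(direction), length(direction) == 1L,
    direction > -180, direction <= 180,
    t_baseline > 0, t_stim > 0, t_post >= 0,
    pulse$onset >= 0, pulse$duration > 0,
    pulse$onset + pulse$duration <= 1, pulse$onset + pulse$duration <= t_baseline
  )
  structure(
    list(direction = direction, condition = condition,
         t_baseline = t_baseline, t_stim = t_stim, t_post = t_post,
         pulse = pulse,
         stim_onset = t_baseline, stim_offset = t_baseline + t_stim,
         duration = t_baseline + t_stim + t_post),
    class = "trial_spec")
}

#' Build a block-pseudorandom survey session
#'
#' Trials are organized in blocks: every (direction, condition) pair occurs
#' exactly once, in random order, before the next round of repetitions
#' begins. The full survey design is 4 directions x 5 conditions x 4
#' repetitions = 80 trials; the 8-direction airflow-only column-sampling
#' design is 8 x 1 x 5 = 40 trials.
#'
#' @param directions Unique stimulus directions, degrees.
#' @param conditions Unique condition labels (subset of
#'   [survey_conditions()]).
#' @param reps Number of repetitions of each pair (>= 1).
#' @param seed Integer seed controlling the pseudorandom block order.
#' @param iti Inter-trial interval, seconds.
#' @param ... Passed to [trial_spec()] (segment durations, pulse).
#' @return A `session_design` list: `trials` (list of `trial_spec`),
#'   `directions`, `conditions`, `reps`, `iti`, and a tidy `table` of the
#'   trial order.
#' @export
build_survey_session <- function(directions, conditions, reps, seed,
                                 iti = 9, ...) {
  stopifnot(length(directions) >= 1, length(conditions) >= 1, reps >= 1)
  if (anyDuplicated(directions)) stop("duplicate stimulus directions")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  pairs <- expand.grid(direction = directions, condition = conditions,
                       stringsAsFactors = FALSE)
  order_tbl <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(reps), function(b) {
      p <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
      p$block <- b
      p
    }))
  })
  order_tbl <- tibble::as_tibble(order_tbl)
  order_tbl$trial <- seq_len(nrow(order_tbl))
  trials <- lapply(seq_len(nrow(order_tbl)), function(i) {
    trial_spec(order_tbl$direction[i], order_tbl$condition[i], ...)
  })
  structure(
    list(trials = trials, directions = directions, conditions = conditions,
         reps = reps, iti = iti, seed = seed,
         table = order_tbl[, c("trial", "block", "direction", "condition")]),
    class = "session_design")
}

#' Parameterize a direction-tuned model neuron
#'
#' A phenomenological generative model of a central-complex columnar neuron:
#' resting potential with optional slow sinusoidal oscillation and Gaussian
#' noise, a baseline firing rate, and a direction-tuned stimulus drive whose
#' modality composition is set by `integration_mode`. Parameter ranges are
#' anchored to intrinsic-property summaries of the surveyed cell types
#' (resting potentials near -30 to -18 mV, input resistances 1.5-10 GOhm,
#' oscillation frequencies 2-4 Hz where present).
#'
#' @param v_rest Resting membrane potential, mV.
#' @param osc_freq Baseline oscillation frequency, Hz (0 = tonic baseline).
#' @param osc_amp Oscillation amplitude, mV.
#' @param noise_sd Gaussian membrane-noise SD per sample, mV (>= 0).
#' @param r_in Input resistance, GOhm.
#' @param baseline_rate Baseline firing rate, spikes/s (>= 0).
#' @param pref_dir Preferred airflow direction, degrees.
#' @param tuning_width Tuning half-width at half-maximum, degrees.
#' @param inhib Contralateral-inhibition depth passed to [tuning_shape()].
#' @param a_air,a_stripe Response amplitudes (spikes/s at the preferred
#'   direction) for airflow and stripe.
#' @param pref_dir_stripe Preferred direction of the visual (stripe)
#'   response, degrees; defaults to `pref_dir` (aligned modalities), but
#'   can differ — visual and airflow preferences need not coincide in the
#'   recorded populations.
#' @param a_odor_gain Multiplicative odor modulation of the airflow term
#'   (< 1 models olfactory suppression of airflow responses).
#' @param integration_mode How simultaneous modalities combine:
#'   `"summation"` adds amplitudes; `"airflow_dominant"` / `"stripe_dominant"`
#'   return only the dominant modality's drive.
#' @param temporal_profile `"tonic"` (sustained drive for the whole stimulus)
#'   or `"transient"` (exponential decay with constant `tau`).
#' @param tau Decay constant of the transient profile, seconds.
#' @param vm_gain Subthreshold depolarization per unit drive, mV/(spikes/s);
#'   negative drive hyperpolarizes (contralateral inhibition in Vm).
#' @param spike_amp Rendered spike height above Vm, mV.
#' @param spike_threshold_true Membrane potential the rendered spikes are
#'   guaranteed to cross, mV.
#' @param tau_m Membrane time constant shaping the test-pulse edges, s.
#' @param refractory Absolute refractory period between spikes, s.
#' @return A `neuron_model` list.
#' @export
neuron_model <- function(v_rest = -25, osc_freq = 2, osc_amp = 1.5,
                         noise_sd = 0.4, r_in = 5, baseline_rate = 5,
                         pref_dir = 45, tuning_width = 60, inhib = 0.25,
                         a_air = 20, a_stripe = 5, pref_dir_stripe = NULL,
                         a_odor_gain = 0.7,
                         integration_mode = c("summation", "airflow_dominant",
                                              "stripe_dominant"),
                         temporal_profile = c("tonic", "transient"), tau = 1,
                         vm_gain = 0.15, spike_amp = 40,
                         spike_threshold_true = 0, tau_m = 0.02,
                         refractory = 0.0025) {
  integration_mode <- match.arg(integration_mode)
  temporal_profile <- match.arg(temporal_profile)
  stopifnot(baseline_rate >= 0, tuning_width > 0, a_odor_gain > 0,
            noise_sd >= 0, tau > 0, r_in > 0, tau_m > 0, refractory >= 0)
  if (is.null(pref_dir_stripe)) pref_dir_stripe <- pref_dir
  structure(
    list(v_rest = v_rest, osc_freq = osc_freq, osc_amp = osc_amp,
         noise_sd = noise_sd, r_in = r_in, baseline_rate = baseline_rate,
         pref_dir = pref_dir, tuning_width = tuning_width, inhib = inhib,
         a_air = a_air, a_stripe = a_stripe,
         pref_dir_stripe = pref_dir_stripe, a_odor_gain = a_odor_gain,
         integration_mode = integration_mode,
         temporal_profile = temporal_profile, tau = tau,
         vm_gain = vm_gain, spike_amp = spike_amp,
         spike_threshold_true = spike_threshold_true, tau_m = tau_m,
         refractory = refractory),
    class = "neuron_model")
}

# Per-modality signed amplitudes (spikes/s) for a condition under the
# neuron's integration mode: summation keeps both terms, dominant modes
# zero the non-dominant modality when both are present; the airflow term is
# multiplied by a_odor_gain when odor is present.
modality_amplitudes <- function(neuron, condition) {
  if (!condition %in% survey_conditions())
    stop("unknown condition: ", condition)
  has_air <- condition != "stripe"
  has_stripe <- condition %in% c("stripe", "stripe+airflow",
                                 "stripe+airflow+odor")
  has_odor <- condition %in% c("airflow+odor", "stripe+airflow+odor")
  air <- if (has_air) neuron$a_air * (if (has_odor) neuron$a_odor_gain else 1)
    else 0
  stripe <- if (has_stripe) neuron$a_stripe else 0
  if (has_air && has_stripe) {
    if (neuron$integration_mode == "airflow_dominant") stripe <- 0
    if (neuron$integration_mode == "stripe_dominant") air <- 0
  }
  c(air = air, stripe = stripe)
}

# Signed drive (spikes/s) at times t; 0 outside the stimulus window. Each
# modality is weighted by its own directional tuning.
stimulus_drive <- function(neuron, trial, t) {
  a <- modality_amplitudes(neuron, trial$condition)
  amp <- a[["air"]] *
    tuning_shape(trial$direction, neuron$pref_dir, neuron$tuning_width,
                 neuron$inhib) +
    a[["stripe"]] *
    tuning_shape(trial$direction, neuron$pref_dir_stripe,
                 neuron$tuning_width, neuron$inhib)
  on <- t >= trial$stim_onset & t < trial$stim_offset
  prof <- numeric(length(t))
  if (neuron$temporal_profile == "tonic") {
    prof[on] <- 1
  } else {
    prof[on] <- exp(-(t[on] - trial$stim_onset) / neuron$tau)
  }
  amp * prof
}

#' Ground-truth expected firing rate of a model neuron
#'
#' The generative rate behind the spike simulator: baseline rate everywhere,
#' plus the direction-tuned, condition-dependent stimulus drive during the
#' stimulus window, floored at zero (negative drive silences the cell).
#'
#' @param neuron A [neuron_model()].
#' @param trial A [trial_spec()].
#' @param t Times within the trial, seconds.
#' @return Expected rate in spikes/s at each `t`.
#' @export
expected_rate <- function(neuron, trial, t) {
  stopifnot(all(t >= 0), all(t <= trial$duration))
  pmax(0, neuron$baseline_rate + stimulus_drive(neuron, trial, t))
}

#' Draw ground-truth spike times for one trial
#'
#' Inhomogeneous-Poisson sampling (thinning) from [expected_rate()].
#'
#' @inheritParams expected_rate
#' @param seed Integer seed; identical seeds give identical spike trains.
#' @return Sorted spike times in seconds.
#' @export
simulate_trial_spikes <- function(neuron, trial, seed) {
  withr::with_seed(seed, draw_spikes(neuron, trial))
}

draw_spikes <- function(neuron, trial) {
  a <- modality_amplitudes(neuron, trial$condition)
  tmax <- max(1, neuron$inhib / (1 - neuron$inhib))  # |tuning| bound
  rmax <- neuron$baseline_rate + tmax * sum(abs(a))
  if (rmax <= 0) return(numeric(0))
  n <- rpois(1, rmax * trial$duration)
  cand <- sort(runif(n, 0, trial$duration))
  keep <- runif(n) < expected_rate(neuron, trial, cand) / rmax
  enforce_refractory(cand[keep], neuron$refractory)
}

# Drop spikes that fall within the absolute refractory period of the
# previous kept spike.
enforce_refractory <- function(spikes, refractory) {
  if (refractory <= 0 || length(spikes) < 2) return(spikes)
  keep <- logical(length(spikes))
  last <- -Inf
  for (i in seq_along(spikes)) {
    if (spikes[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- spikes[i]
    }
  }
  spikes[keep]
}

#' Simulate one trial's membrane-voltage trace
#'
#' Renders resting potential, baseline oscillation, Gaussian noise, the
#' subthreshold tuned drive, the -2 pA test-pulse deflection (steady state
#' `current * r_in` mV, with exponential edges at the membrane time
#' constant), and spikes drawn from [expected_rate()] as 2 ms triangular
#' depolarizations of height `spike_amp`.
#'
#' @inheritParams simulate_trial_spikes
#' @param fs Sampling rate, Hz.
#' @param neuron_id,fly_id Identifier strings stored in the trace.
#' @return A `voltage_trace`: `samples` (mV), `fs`, `trial`, `spikes`
#'   (ground-truth spike times), `neuron_id`, `fly_id`, `seed`.
#' @export
simulate_trial_vm <- function(neuron, trial, seed, fs = 10000,
                              neuron_id = "cell1", fly_id = "fly1") {
  stopifnot(neuron$noise_sd >= 0, fs > 0)
  n <- round(trial$duration * fs)
  t <- (seq_len(n) - 1) / fs
  out <- withr::with_seed(seed, {
    spikes <- draw_spikes(neuron, trial)
    phase <- runif(1, 0, 2 * pi)     # oscillation is not stimulus-locked
    noise <- if (neuron$noise_sd > 0) rnorm(n, 0, neuron$noise_sd) else
      numeric(n)
    list(spikes = spikes, phase = phase, noise = noise)
  })
  v <- neuron$v_rest +
    neuron$osc_amp * sin(2 * pi * neuron$osc_freq * t + out$phase) +
    neuron$vm_gain * stimulus_drive(neuron, trial, t) +
    pulse_deflection(trial$pulse, t, neuron$r_in, neuron$tau_m) +
    out$noise
  v <- render_spikes(v, out$spikes, fs, neuron$spike_amp,
                     neuron$spike_threshold_true)
  structure(
    list(samples = v, fs = fs, trial = trial, spikes = out$spikes,
         neuron_id = neuron_id, fly_id = fly_id, seed = seed),
    class = "voltage_trace")
}

# Test-pulse Vm deflection: steady state I * R (pA * GOhm = mV), exponential
# onset/offset with membrane time constant tau_m.
pulse_deflection <- function(pulse, t, r_in, tau_m) {
  dv <- pulse$current * r_in
  on <- pulse$onset
  off <- pulse$onset + pulse$duration
  d <- numeric(length(t))
  during <- t >= on & t < off
  after <- t >= off
  d[during] <- dv * (1 - exp(-(t[during] - on) / tau_m))
  v_off <- dv * (1 - exp(-pulse$duration / tau_m))
  d[after] <- v_off * exp(-(t[after] - off) / tau_m)
  d
}

# Add fixed-width triangular spike waveforms; peak clears the nominal
# threshold by construction since spike_amp >> threshold - v_rest.
render_spikes <- function(v, spikes, fs, spike_amp, threshold) {
  if (length(spikes) == 0) return(v)
  half <- max(1L, round(0.001 * fs))           # 2 ms total width
  shape <- spike_amp * (1 - abs(seq(-half, half) / half))
  n <- length(v)
  for (s in spikes) {
    i0 <- round(s * fs) + 1L
    idx <- (i0 - half):(i0 + half)
    ok <- idx >= 1L & idx <= n
    v[idx[ok]] <- v[idx[ok]] + shape[ok]
  }
  v
}

#' Time base of a voltage trace
#' @param trace A `voltage_trace`.
#' @return Sample times in seconds (first sample at t = 0).
#' @export
trace_time <- function(trace) (seq_along(trace$samples) - 1) / trace$fs

#' Simulate a full recording session
#'
#' Runs [simulate_trial_vm()] for every trial of a session design, deriving
#' one sub-seed per trial from `seed`.
#'
#' @param neuron A [neuron_model()].
#' @param session A [build_survey_session()] design.
#' @param seed Integer session seed.
#' @inheritParams simulate_trial_vm
#' @return List of `voltage_trace` objects, one per trial, in session order.
#' @export
simulate_session <- function(neuron, session, seed, fs = 10000,
                             neuron_id = "cell1", fly_id = "fly1") {
  sub <- trial_seeds(seed, length(session$trials))
  lapply(seq_along(session$trials), function(i) {
    simulate_trial_vm(neuron, session$trials[[i]], seed = sub[i], fs = fs,
                      neuron_id = neuron_id, fly_id = fly_id)
  })
}

# Deterministic per-trial sub-seeds that stay within 32-bit integer range.
trial_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}
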