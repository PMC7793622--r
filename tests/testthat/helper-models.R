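# Deterministic model: no oscillation, no noise, no baseline spiking.
quiet_neuron <- function(...) {
  neuron_model(osc_amp = 0, noise_sd = 0, baseline_rate = 0, ...)
}

# Spike-train table for the integration analysis: simulated spike trains for
# every (direction, condition, rep) cell of a survey-style design.
spike_train_table <- function(neuron, conditions, seed, reps = 4,
                              directions = survey_directions()) {
  g <- expand.grid(direction = directions, condition = conditions,
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  g$spikes <- lapply(seq_len(nrow(g)), function(i) {
    simulate_trial_spikes(neuron,
                          trial_spec(g$direction[i], g$condition[i]),
                          seed = seed * 10000 + i)
  })
  tibble::as_tibble(g)
}

# Add a triangular spike waveform (2 ms, fixed height) at given times.
inject_spikes <- function(v, times, fs, amp = 40) {
  half <- max(1L, round(0.001 * fs))
  shape <- amp * (1 - abs(seq(-half, half) / half))
  for (s in times) {
    i0 <- round(s * fs) + 1L
    idx <- (i0 - half):(i0 + half)
    ok <- idx >= 1L & idx <= length(v)
    v[idx[ok]] <- v[idx[ok]] + shape[ok]
  }
  v
}

# Mirror a perturbation schedule: swap left and right slips.
mirror_schedule <- function(sched) {
  swap <- c(slip_right_short = "slip_left_short",
            slip_left_short = "slip_right_short",
            slip_right_long = "slip_left_long",
            slip_left_long = "slip_right_long")
  is_slip <- sched$kind == "slip"
  sched$type[is_slip] <- unname(swap[sched$type[is_slip]])
  sched$sign[is_slip] <- -sched$sign[is_slip]
  sched
}
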