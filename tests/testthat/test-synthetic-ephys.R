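test_that("survey session designs have the documented sizes", {
  s <- build_survey_session(survey_directions(), survey_conditions(),
                            reps = 4, seed = 1)
  expect_length(s$trials, 80)
  expect_equal(nrow(unique(s$table[, c("direction", "condition")])), 20)

  s8 <- build_survey_session(seq(-135, 180, by = 45), "airflow",
                             reps = 5, seed = 1)
  expect_length(s8$trials, 40)

  expect_length(build_survey_session(0, "airflow", 1, seed = 1)$trials, 1)
})

test_that("sessions are block-pseudorandom and seed-reproducible", {
  dirs <- survey_directions()
  conds <- c("stripe", "airflow", "stripe+airflow")
  for (seed in 1:5) {
    s <- build_survey_session(dirs, conds, reps = 3, seed = seed)
    bs <- nrow(s$table) / 3
    full <- sort(paste(rep(dirs, times = length(conds)),
                       rep(conds, each = length(dirs))))
    for (b in 1:3) {
      blk <- s$table[s$table$block == b, ]
      expect_equal(sort(paste(blk$direction, blk$condition)), full)
      expect_equal(nrow(blk), bs)
    }
  }
  expect_identical(build_survey_session(dirs, conds, 2, seed = 9)$table,
                   build_survey_session(dirs, conds, 2, seed = 9)$table)
  expect_error(build_survey_session(c(0, 0), "airflow", 1, seed = 1),
               "duplicate")
  expect_error(build_survey_session(0, c("airflow", "airflow"), 1, seed = 1),
               "duplicate")
})

test_that("expected rate combines modalities per integration mode", {
  tsum <- trial_spec(45, "stripe+airflow")
  nm <- neuron_model(pref_dir = 45, a_air = 6, a_stripe = 2,
                     integration_mode = "summation")
  expect_equal(expected_rate(nm, tsum, 5) - nm$baseline_rate, 8)

  nmd <- neuron_model(pref_dir = 45, a_air = 6, a_stripe = 2,
                      integration_mode = "airflow_dominant")
  expect_equal(expected_rate(nmd, tsum, 5) - nmd$baseline_rate, 6)

  nms <- neuron_model(pref_dir = 45, a_air = 6, a_stripe = 2,
                      integration_mode = "stripe_dominant")
  expect_equal(expected_rate(nms, tsum, 5) - nms$baseline_rate, 2)

  # anti-preferred direction: drive follows the tuning function, which is
  # negative there for inhib > 0
  nmn <- neuron_model(pref_dir = 45, tuning_width = 40, inhib = 0.3,
                      a_air = 10, baseline_rate = 20)
  drive <- expected_rate(nmn, trial_spec(-135, "airflow"), 5) - 20
  expect_equal(drive,
               10 * tuning_shape(-135, 45, 40, 0.3))
  expect_lt(drive, 0)

  # odor multiplies the airflow term
  nmo <- neuron_model(pref_dir = 0, a_air = 10, a_odor_gain = 0.7)
  expect_equal(expected_rate(nmo, trial_spec(0, "airflow+odor"), 5) -
                 nmo$baseline_rate, 7)
  expect_error(windcompass:::modality_amplitudes(nmo, "flicker"),
               "unknown condition")
})

test_that("rate is floored at zero and baseline outside the stimulus", {
  nm <- neuron_model(pref_dir = 45, tuning_width = 30, inhib = 0.4,
                     a_air = 50, baseline_rate = 3)
  tr <- trial_spec(-135, "airflow")
  expect_equal(expected_rate(nm, tr, c(1, 9, 11.5)), rep(3, 3))
  expect_equal(expected_rate(nm, tr, 6), 0)   # deep inhibition clips at 0
})

test_that("simulated traces obey Ohm's law and are flat when silenced", {
  nm <- quiet_neuron(r_in = 10)
  tr <- trial_spec(180, "stripe")     # far from pref, a_stripe tuned away
  vm <- simulate_trial_vm(nm, tr, seed = 1)
  expect_equal(input_resistance(vm), 10, tolerance = 1e-2)

  # outside the pulse (and with no drive at all) the trace sits at v_rest
  nm0 <- quiet_neuron(a_air = 0, a_stripe = 0)
  vm0 <- simulate_trial_vm(nm0, trial_spec(0, "airflow"), seed = 2)
  t <- trace_time(vm0)
  expect_true(all(abs(vm0$samples[t > 1.5] - nm0$v_rest) < 1e-6))
  expect_length(vm0$samples, 12 * vm0$fs)
  expect_true(all(is.finite(vm0$samples)))
})

test_that("simulation is deterministic under a fixed seed", {
  nm <- neuron_model()
  tr <- trial_spec(90, "airflow")
  a <- simulate_trial_vm(nm, tr, seed = 77)
  b <- simulate_trial_vm(nm, tr, seed = 77)
  expect_identical(a$samples, b$samples)
  expect_identical(a$spikes, b$spikes)
  expect_identical(simulate_trial_spikes(nm, tr, seed = 77), a$spikes)
  c <- simulate_trial_vm(nm, tr, seed = 78)
  expect_false(identical(a$samples, c$samples))
  expect_error(neuron_model(noise_sd = -1))
})

test_that("spike counts match the integral of the expected rate", {
  # pure inhomogeneous-Poisson model (no refractory thinning)
  nm <- neuron_model(refractory = 0)
  tr <- trial_spec(45, "airflow")
  t <- seq(4, 8, by = 1e-3)
  expected <- mean(expected_rate(nm, tr, t)) * 4
  counts <- vapply(1:120, function(s) {
    sp <- simulate_trial_spikes(nm, tr, seed = s)
    sum(sp >= 4 & sp < 8)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("refractory thinning enforces minimum spike spacing", {
  nm <- neuron_model(baseline_rate = 80, refractory = 0.0025)
  sp <- simulate_trial_spikes(nm, trial_spec(45, "airflow"), seed = 5)
  expect_true(all(diff(sp) >= 0.0025))
  expect_true(all(sp >= 0 & sp <= 12))
})

test_that("a baseline oscillation set in the generator is recovered", {
  nm <- neuron_model(osc_freq = 2, osc_amp = 2, noise_sd = 0.3,
                     baseline_rate = 0)
  traces <- lapply(1:4, function(s)
    simulate_trial_vm(nm, trial_spec(90, "airflow"), seed = s))
  bp <- baseline_profile(traces)
  expect_equal(bp$osc_freq, 2, tolerance = 0.3)
})
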