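test_that("fixation metrics match closed forms", {
  fm <- fixation_metrics(rep(180, 1000))
  expect_equal(fm$mean_orientation, 180)
  expect_equal(fm$strength, 1)
  expect_equal(fm$toward_fraction, 0)

  # uniform over 8 equally spaced angles: no resultant, quadrant = 1/4
  angles <- seq(-135, 180, by = 45)
  fm8 <- fixation_metrics(rep(angles, 50))
  expect_equal(fm8$strength, 0, tolerance = 1e-12)
  expect_equal(fm8$toward_fraction, 0.25)

  fm45 <- fixation_metrics(rep(c(45, -45), 100))
  expect_equal(fm45$mean_orientation, 0)
  expect_equal(fm45$strength, cos(pi / 4), tolerance = 1e-12)
})

test_that("fixation strength is 1 only for identical samples", {
  for (seed in 1:5) {
    th <- withr::with_seed(seed, runif(500, -180, 180))
    s <- fixation_metrics(th)$strength
    expect_true(s >= 0 && s < 1)
  }
  expect_equal(fixation_metrics(rep(-37.3, 10))$strength, 1)
})

test_that("slip responses integrate dWBA over the post-slip window", {
  still <- fly_agent(k = 0, noise_sd = 0, pause_bias = 0)
  ar <- arena_config()
  rec <- run_session(still, ar, make_schedule(2, seed = 4), seed = 1)
  sr <- slip_responses(rec)
  expect_true(all(sr$integrated$integrated == 0))
  expect_equal(nrow(sr$integrated), 8)      # 4 slip types x 2 reps
  expect_equal(sr$dropped, 0)

  # inject a constant leftward dWBA of -1 for 5 s after right slips
  fs <- ar$fs
  rights <- rec$schedule[rec$schedule$type %in%
                           c("slip_right_short", "slip_right_long"), ]
  for (r in seq_len(nrow(rights))) {
    i0 <- round(rights$onset[r] * fs) + 1L
    rec$data$dwba[(i0 + 1):(i0 + 5 * fs)] <- -1
  }
  sr2 <- slip_responses(rec)
  ir <- sr2$integrated
  expect_equal(ir$integrated[ir$sign == 1], rep(-5, 4))
  expect_equal(ir$integrated[ir$sign == -1], rep(0, 4))

  # timecourse window is 1 s pre to 5 s post at 50 Hz
  tc <- sr2$timecourses
  expect_equal(range(tc$time), c(-1, 5))
  expect_equal(sum(tc$type == "slip_right_long"), 6 * fs + 1)
})

test_that("a steering fly makes corrective turns opposite the slip", {
  rec <- run_session(fly_agent(noise_sd = 0), arena_config(),
                     make_schedule(3, seed = 12), seed = 2)
  ir <- slip_responses(rec)$integrated
  agg <- tapply(ir$integrated, sign(ir$slip_deg), mean)
  expect_lt(agg[["1"]], 0)    # right slip -> leftward (negative) turning
  expect_gt(agg[["-1"]], 0)
})

test_that("correction fraction is a gain-converted restoration ratio", {
  ar <- arena_config()
  to_integral <- function(orient_change) orient_change / (ar$gain * ar$fs)
  # perfect correction: turning exactly undoes the slip
  expect_equal(correction_fraction(to_integral(-63.36), 63.36, ar), 1)
  expect_equal(correction_fraction(to_integral(c(-14.4, 14.4)),
                                   c(14.4, -14.4), ar), 1)
  expect_equal(correction_fraction(0, 63.36, ar), 0)
  # anti-corrective: same sign and magnitude as the slip
  expect_equal(correction_fraction(to_integral(14.4), 14.4, ar), -1)
  expect_error(correction_fraction(1, 0, ar))

  # end-to-end on a record: inject post-slip dWBA whose gain-converted
  # integral exactly undoes each slip -> correction fraction exactly 1
  still <- fly_agent(k = 0, noise_sd = 0, pause_bias = 0)
  rec0 <- run_session(still, ar, make_schedule(2, seed = 7), seed = 1)
  slips <- rec0$schedule[rec0$schedule$kind == "slip", ]
  for (r in seq_len(nrow(slips))) {
    i0 <- round(slips$onset[r] * ar$fs) + 1L
    disp <- apply_slip(slips$n_samples[r], slips$sign[r], ar)
    # spread the corrective turn over the 2 s after the slip
    rec0$data$dwba[(i0 + 1):(i0 + 2 * ar$fs)] <-
      -disp / (ar$gain * 2 * ar$fs)
  }
  cf0 <- correction_fractions(rec0)
  expect_equal(cf0$correction_fraction, rep(1, 2), tolerance = 1e-9)

  # a closed-loop error-correcting agent restores its heading; its
  # correction fraction sits near 1 (slightly above, because steering
  # effort during the open-loop slip itself is part of the integral)
  rec <- run_session(fly_agent(k = 0.5, noise_sd = 0, latency = 0),
                     arena_config(), make_schedule(3, seed = 2), seed = 3,
                     orientation0 = 180)
  cf <- correction_fractions(rec)
  expect_true(all(cf$correction_fraction > 0.9 &
                    cf$correction_fraction < 1.3))
})

test_that("pause responses are sign-adjusted toward the source", {
  # agent that turns toward the source when the airflow pauses
  ag <- fly_agent(k = 0.3, noise_sd = 0, pause_bias = 5)
  for (ori0 in c(120, -120)) {
    rec <- run_session(ag, arena_config(), make_schedule(2, seed = 6),
                       seed = 4, orientation0 = ori0)
    pr <- pause_responses(rec)
    during <- pr$timecourses[pr$timecourses$type == "pause_long" &
                               pr$timecourses$time > 0 &
                               pr$timecourses$time <= 2, ]
    expect_gt(mean(during$mean), 0)   # toward-positive on both sides
    expect_true(all(pr$integrated$integrated > 0))
  }
})

test_that("mirror-image sessions give identical adjusted pause responses", {
  ag <- fly_agent(k = 0.3, noise_sd = 0, pause_bias = 5)
  ar <- arena_config()
  schedA <- make_schedule(2, seed = 31)
  schedB <- mirror_schedule(schedA)
  recA <- run_session(ag, ar, schedA, seed = 1, orientation0 = 60)
  recB <- run_session(ag, ar, schedB, seed = 1, orientation0 = -60)
  prA <- pause_responses(recA)$timecourses
  prB <- pause_responses(recB)$timecourses
  expect_equal(prB$mean, prA$mean, tolerance = 1e-6)
})

test_that("response histograms collapse across slip direction", {
  h <- response_histogram(c(30, -30), slip_sign = c(1, -1))
  expect_equal(nrow(h[h$count > 0, ]), 1)   # both land in the same bin
  expect_equal(h$count[h$count > 0], 2)

  h0 <- response_histogram(rep(0, 5))
  expect_equal(h0$prob[h0$mid == 0], 1)

  set.seed(2)
  hr <- response_histogram(rnorm(500, 0, 40))
  expect_equal(sum(hr$prob), 1)
  expect_error(response_histogram(1:3, bin_width = 0))
})
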