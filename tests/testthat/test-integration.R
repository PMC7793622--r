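test_that("summation points compare multimodal to summed unimodal means", {
  resp <- tibble::tibble(
    direction = rep(c(0, 90), each = 3),
    condition = rep(c("stripe", "airflow", "stripe+airflow"), 2),
    response = c(2, 6, 8, 1, 4, 5))
  pts <- summation_points(resp)
  expect_equal(pts$predicted, c(8, 5))
  expect_equal(pts$observed, c(8, 5))

  expect_error(summation_points(resp[resp$condition != "stripe", ]),
               "must be present")
})

test_that("summation points expose the generator's integration algebra", {
  dirs <- survey_directions()
  conds <- c("stripe", "airflow", "stripe+airflow")
  resp_table <- function(nm) {
    g <- expand.grid(direction = dirs, condition = conds,
                     stringsAsFactors = FALSE)
    g$response <- vapply(seq_len(nrow(g)), function(i) {
      tr <- trial_spec(g$direction[i], g$condition[i])
      expected_rate(nm, tr, 5) - nm$baseline_rate
    }, numeric(1))
    g
  }
  # summation mode: exactly on the diagonal (baseline_rate high enough that
  # the rate floor never engages)
  nm_sum <- neuron_model(integration_mode = "summation", baseline_rate = 30,
                         pref_dir_stripe = -45)
  pts <- summation_points(resp_table(nm_sum))
  expect_equal(pts$observed, pts$predicted, tolerance = 1e-10)

  # airflow-dominant: off the diagonal by exactly the stripe response
  nm_dom <- neuron_model(integration_mode = "airflow_dominant",
                         baseline_rate = 30, pref_dir_stripe = -45)
  pts_d <- summation_points(resp_table(nm_dom))
  stripe <- resp_table(nm_dom)
  stripe <- stripe$response[stripe$condition == "stripe"]
  expect_equal(pts_d$predicted - pts_d$observed, stripe, tolerance = 1e-10)

  # trimodal variant: predicted = stripe + odorized-airflow means
  g3 <- expand.grid(direction = dirs,
                    condition = c("stripe", "airflow+odor",
                                  "stripe+airflow+odor"),
                    stringsAsFactors = FALSE)
  g3$response <- vapply(seq_len(nrow(g3)), function(i) {
    expected_rate(nm_sum, trial_spec(g3$direction[i], g3$condition[i]), 5) -
      nm_sum$baseline_rate
  }, numeric(1))
  pts3 <- summation_points(g3, trimodal = TRUE)
  expect_equal(pts3$observed, pts3$predicted, tolerance = 1e-10)
})

# Synthetic PSTH table on a regular grid for direct similarity tests.
make_psth_tbl <- function(rate_fun, conds = c("stripe+airflow", "airflow",
                                              "stripe"),
                          dirs = c(-90, 0, 90, 180),
                          time = seq(0.005, 11.995, by = 0.01)) {
  dplyr::bind_rows(lapply(conds, function(cn)
    dplyr::bind_rows(lapply(dirs, function(d)
      tibble::tibble(condition = cn, direction = d, time = time,
                     rate = rate_fun(cn, d, time))))))
}

test_that("similarity is 1 for identical timecourses and flags degeneracy", {
  f <- function(cn, d, t) {
    base <- switch(cn, "stripe+airflow" = , "airflow" = sin(2 * pi * t / 3),
                   "stripe" = cos(2 * pi * t / 4))
    (1 + d / 180) * base
  }
  s <- similarity_coefficients(make_psth_tbl(f))
  expect_equal(s$rho_air, 1, tolerance = 1e-12)
  expect_false(s$degenerate)

  # flat stripe response: degenerate, rho reported as NA, not 0
  f2 <- function(cn, d, t) if (cn == "stripe") rep(0, length(t)) else
    sin(2 * pi * t / 3)
  s2 <- similarity_coefficients(make_psth_tbl(f2), baseline_window = NULL)
  expect_true(s2$degenerate)
  expect_true(is.na(s2$rho_stripe))
  expect_equal(s2$rho_air, 1, tolerance = 1e-12)
})

test_that("an equal-power orthogonal sum gives rho = 1/sqrt(2)", {
  # x and y orthogonal with equal power over whole periods of the
  # truncated (4-12 s) segment
  f <- function(cn, d, t) {
    ph <- d / 90  # any per-direction variation, shared across conditions
    switch(cn,
           "airflow" = sin(2 * pi * (t - 4) / 2),
           "stripe" = cos(2 * pi * (t - 4) / 2),
           "stripe+airflow" = sin(2 * pi * (t - 4) / 2) +
             cos(2 * pi * (t - 4) / 2)) + 0 * ph
  }
  s <- similarity_coefficients(make_psth_tbl(f), baseline_window = NULL)
  expect_equal(s$rho_air, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(s$rho_stripe, 1 / sqrt(2), tolerance = 1e-6)
})

test_that("similarity is invariant to direction order and multimodal scale", {
  f <- function(cn, d, t) {
    set.seed(abs(d) + nchar(cn))
    stats::approx(seq(0, 12, length.out = 25), rnorm(25), xout = t)$y
  }
  tbl <- make_psth_tbl(f)
  s1 <- similarity_coefficients(tbl, dir_order = c(-90, 0, 90, 180))
  s2 <- similarity_coefficients(tbl, dir_order = c(180, 90, -90, 0))
  expect_equal(s1$rho_air, s2$rho_air, tolerance = 1e-12)
  expect_equal(s1$rho_stripe, s2$rho_stripe, tolerance = 1e-12)

  tbl_scaled <- tbl
  sel <- tbl_scaled$condition == "stripe+airflow"
  tbl_scaled$rate[sel] <- 3.7 * tbl_scaled$rate[sel]
  s3 <- similarity_coefficients(tbl_scaled)
  expect_equal(s3$rho_air, s1$rho_air, tolerance = 1e-12)
  expect_equal(s3$rho_stripe, s1$rho_stripe, tolerance = 1e-12)
})

test_that("full-trace and spike-train routes agree on the coefficients", {
  nm <- neuron_model(integration_mode = "summation", a_air = 10,
                     a_stripe = 10, pref_dir_stripe = -45, osc_amp = 0)
  conds <- c("stripe+airflow", "airflow", "stripe")
  g <- expand.grid(direction = survey_directions(), condition = conds,
                   rep = 1:2, stringsAsFactors = FALSE)
  seeds <- seq_len(nrow(g)) + 400
  # route 1: ground-truth spike trains
  g$spikes <- lapply(seq_len(nrow(g)), function(i)
    simulate_trial_spikes(nm, trial_spec(g$direction[i], g$condition[i]),
                          seed = seeds[i]))
  s_truth <- similarity_coefficients(condition_psths(tibble::as_tibble(g)))
  # route 2: simulate Vm with the same seeds, detect spikes, rebuild PSTHs
  g2 <- g
  g2$spikes <- lapply(seq_len(nrow(g)), function(i) {
    vm <- simulate_trial_vm(nm, trial_spec(g$direction[i], g$condition[i]),
                            seed = seeds[i])
    as.numeric(detect_spikes(vm))
  })
  s_det <- similarity_coefficients(condition_psths(tibble::as_tibble(g2)))
  expect_equal(s_det$rho_air, s_truth$rho_air, tolerance = 0.05)
  expect_equal(s_det$rho_stripe, s_truth$rho_stripe, tolerance = 0.05)
})
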