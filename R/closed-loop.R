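#' Closed-loop arena configuration
#'
#' The tethered-flight arena: the difference in wingbeat angles (dWBA,
#' positive = rightward turn) is multiplied by a static gain and drives a
#' stepper motor that rotates the airflow source around the fly, at a 50 Hz
#' control loop. The gain is applied once per control sample (degrees of
#' source rotation per unit dWBA per sample), and the motor speed cap
#' applies both in closed loop and during open-loop slips.
#'
#' @param fs Control-loop rate, Hz.
#' @param gain Degrees of rotation per unit dWBA per sample.
#' @param motor_max Maximum motor speed, degrees/s.
#' @param source_angle0 Initial world-frame angle of the airflow source,
#'   degrees (the source is the 0 reference of virtual orientation).
#' @return An `arena_config` list.
#' @export
arena_config <- function(fs = 50, gain = 0.04, motor_max = 144,
                         source_angle0 = 0) {
  stopifnot(fs > 0, gain >= 0, motor_max > 0)
  structure(list(fs = fs, gain = gain, motor_max = motor_max,
                 source_angle0 = source_angle0),
            class = "arena_config")
}

# The six open-loop perturbation types: airflow pauses and constant-speed
# source slips at the motor maximum.
perturbation_types <- function() {
  tibble::tibble(
    type = c("pause_long", "pause_short", "slip_right_short",
             "slip_right_long", "slip_left_short", "slip_left_long"),
    kind = c("pause", "pause", "slip", "slip", "slip", "slip"),
    duration_s = c(2, 0.15, NA, NA, NA, NA),
    n_samples = c(NA, NA, 5, 22, 5, 22),
    sign = c(NA, NA, 1, 1, -1, -1))
}

#' Build a pseudorandom perturbation schedule
#'
#' A testing session is divided into fixed-length trials, each beginning
#' with one of six open-loop perturbations: long (2 s) and short airflow
#' pauses, and short (5-sample, 14.4 deg) and long (22-sample, 63.36 deg)
#' slips of the airflow source to the left or right. Each type occurs
#' `reps_per_type` times in pseudorandom order (10 repetitions each over a
#' 20 min session in the standard design).
#'
#' @param reps_per_type Repetitions of each of the 6 types (>= 1).
#' @param seed Integer seed for the pseudorandom order.
#' @param trial_len Trial length, seconds.
#' @param onset_offset Perturbation onset within its trial, seconds (leaves
#'   a pre-perturbation analysis window).
#' @return A `perturbation_schedule` tibble: `trial`, `type`, `kind`,
#'   `onset` (s from session start), `duration_s`, `n_samples`, `sign`;
#'   with attributes `trial_len` and `reps_per_type`.
#' @export
make_schedule <- function(reps_per_type, seed, trial_len = 20,
                          onset_offset = 1) {
  stopifnot(reps_per_type >= 1, trial_len > onset_offset)
  types <- perturbation_types()
  order <- withr::with_seed(seed, {
    unlist(lapply(seq_len(reps_per_type), function(b)
      sample(types$type)))
  })
  sched <- types[match(order, types$type), ]
  sched$trial <- seq_along(order)
  sched$onset <- (sched$trial - 1) * trial_len + onset_offset
  sched <- sched[, c("trial", "type", "kind", "onset", "duration_s",
                     "n_samples", "sign")]
  structure(sched, class = c("perturbation_schedule", class(sched)),
            trial_len = trial_len, reps_per_type = reps_per_type)
}

#' Open-loop slip displacement
#'
#' A slip drives the source continuously at the motor maximum for a fixed
#' number of control samples, ignoring the fly's input: 5 samples = 14.4
#' degrees, 22 samples = 63.36 degrees at the default arena.
#'
#' @param n_samples Number of control samples driven (>= 0).
#' @param direction_sign +1 for rightward, -1 for leftward.
#' @param arena An [arena_config()].
#' @return Signed displacement, degrees.
#' @export
apply_slip <- function(n_samples, direction_sign, arena = arena_config()) {
  stopifnot(n_samples >= 0, direction_sign %in% c(-1, 1))
  direction_sign * arena$motor_max * n_samples / arena$fs
}

#' One closed-loop orientation update
#'
#' The per-sample update rule: orientation increases by `gain * dwba`,
#' clamped to the motor speed cap (`motor_max / fs` degrees per sample),
#' then wraps to (-180, 180].
#'
#' @param orientation Current virtual orientation, degrees.
#' @param dwba Wingbeat-angle difference this sample (positive = rightward).
#' @param arena An [arena_config()].
#' @return Updated orientation, degrees. Vectorized over both inputs.
#' @export
step_orientation <- function(orientation, dwba, arena = arena_config()) {
  cap <- arena$motor_max / arena$fs
  wrap_angle(orientation + pmin(pmax(arena$gain * dwba, -cap), cap))
}

#' Parameterize a phenomenological fly steering policy
#'
#' The agent steers toward a preferred flow-relative orientation
#' (downwind, 180 degrees, by default) with proportional gain on the
#' orientation error, motor noise, and a reaction latency. While the
#' airflow is off it cannot sense flow direction; instead it applies a
#' fixed-magnitude dWBA bias directed toward the airflow source's last
#' bearing (tethered flies briefly turn toward the source when flow
#' pauses).
#'
#' @param theta_goal Preferred flow-relative orientation, degrees.
#' @param k Steering gain, dWBA units per degree of orientation error.
#' @param noise_sd Motor noise SD, dWBA units per sample.
#' @param pause_bias Magnitude of the toward-source dWBA bias during
#'   airflow pauses.
#' @param latency Reaction latency, control samples.
#' @return A `fly_agent` list.
#' @export
fly_agent <- function(theta_goal = 180, k = 0.3, noise_sd = 2,
                      pause_bias = 3, latency = 3) {
  stopifnot(k >= 0, latency >= 0, noise_sd >= 0)
  structure(list(theta_goal = theta_goal, k = k, noise_sd = noise_sd,
                 pause_bias = pause_bias, latency = round(latency)),
            class = "fly_agent")
}

# Sign that turns the fly toward the source (at 0): negative orientations
# need rightward (positive) dWBA.
toward_sign <- function(orientation) -sign(orientation)

#' Run a closed-loop behavioral session
#'
#' Simulates the full control loop: each sample, the agent produces a dWBA
#' from the (latency-delayed) orientation error, the arena integrates
#' `gain * dwba` under the motor cap, and scheduled perturbations override
#' the loop — pauses switch the airflow off (the agent steers blind with
#' its pause bias; the loop keeps running), slips drive the source
#' open-loop at the motor maximum, ignoring the fly.
#'
#' @param agent A [fly_agent()].
#' @param arena An [arena_config()].
#' @param schedule A [make_schedule()] perturbation schedule.
#' @param seed Integer seed for the motor noise.
#' @param orientation0 Starting virtual orientation, degrees.
#' @param fly_id,genotype_label Metadata stored in the record.
#' @return A `behavior_record`: `data` tibble (`t`, `dwba`, `orientation`,
#'   `airflow_on`, `in_slip`, `trial`, `trial_type`) plus the `schedule`,
#'   `arena`, `agent`, `orientation0`, ids and `seed`.
#' @export
run_session <- function(agent, arena, schedule, seed, orientation0 = 0,
                        fly_id = "fly1", genotype_label = "control") {
  fs <- arena$fs
  trial_len <- attr(schedule, "trial_len")
  n <- round(nrow(schedule) * trial_len * fs)
  ann <- annotate_samples(schedule, arena, n)
  noise <- withr::with_seed(seed, rnorm(n, 0, agent$noise_sd))
  ori <- numeric(n)
  dwba <- numeric(n)
  cap <- arena$motor_max / fs
  th <- orientation0
  for (i in seq_len(n)) {
    j <- max(1L, i - agent$latency)
    th_del <- if (j == 1L) orientation0 else ori[j - 1L]
    dwba[i] <- if (ann$airflow_on[i]) {
      agent$k * wrap_angle(agent$theta_goal - th_del) + noise[i]
    } else {
      agent$pause_bias * toward_sign(th_del) + noise[i]
    }
    dth <- if (ann$in_slip[i]) ann$slip_step[i] else
      min(max(arena$gain * dwba[i], -cap), cap)
    th <- wrap_angle(th + dth)
    ori[i] <- th
  }
  data <- tibble::tibble(
    t = seq_len(n) / fs, dwba = dwba, orientation = ori,
    airflow_on = ann$airflow_on, in_slip = ann$in_slip,
    trial = ann$trial, trial_type = ann$trial_type)
  structure(
    list(data = data, schedule = schedule, arena = arena, agent = agent,
         orientation0 = orientation0, fly_id = fly_id,
         genotype_label = genotype_label, seed = seed),
    class = "behavior_record")
}

# Per-sample annotation of the session: airflow state, slip override steps,
# and trial labels. Sample i covers time ((i-1)/fs, i/fs].
annotate_samples <- function(schedule, arena, n) {
  fs <- arena$fs
  trial_len <- attr(schedule, "trial_len")
  airflow_on <- rep(TRUE, n)
  in_slip <- rep(FALSE, n)
  slip_step <- numeric(n)
  trial <- pmin(floor((seq_len(n) - 1) / (trial_len * fs)) + 1,
                nrow(schedule))
  trial_type <- schedule$type[trial]
  for (r in seq_len(nrow(schedule))) {
    i0 <- round(schedule$onset[r] * fs) + 1L
    if (schedule$kind[r] == "pause") {
      idx <- i0:min(n, i0 + round(schedule$duration_s[r] * fs) - 1L)
      airflow_on[idx] <- FALSE
    } else {
      idx <- i0:min(n, i0 + schedule$n_samples[r] - 1L)
      in_slip[idx] <- TRUE
      slip_step[idx] <- schedule$sign[r] * arena$motor_max / fs
    }
  }
  list(airflow_on = airflow_on, in_slip = in_slip, slip_step = slip_step,
       trial = trial, trial_type = trial_type)
}

#' Reconstruct the orientation series from dWBA and the schedule
#'
#' Recomputes virtual orientation sample-by-sample from the stored dWBA,
#' the arena parameters and the perturbation schedule. For a valid record
#' the reconstruction is exact (bit-identical update rule), which is the
#' consistency invariant validated when records are read from disk.
#'
#' @param record A `behavior_record`.
#' @return Numeric orientation series, degrees.
#' @export
reconstruct_orientation <- function(record) {
  arena <- record$arena
  n <- nrow(record$data)
  ann <- annotate_samples(record$schedule, arena, n)
  cap <- arena$motor_max / arena$fs
  ori <- numeric(n)
  th <- record$orientation0
  dwba <- record$data$dwba
  for (i in seq_len(n)) {
    dth <- if (ann$in_slip[i]) ann$slip_step[i] else
      min(max(arena$gain * dwba[i], -cap), cap)
    th <- wrap_angle(th + dth)
    ori[i] <- th
  }
  ori
}
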