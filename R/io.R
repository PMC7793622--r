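#' Write a simulated recording session to a directory container
#'
#' One delimited-text trace file per trial (columns `t`, `vm`) plus a JSON
#' metadata table (`trials.json`) holding fly/neuron identifiers, stimulus
#' direction and condition, seed and sampling rate for every trial.
#'
#' @param traces List of `voltage_trace` objects (e.g. from
#'   [simulate_session()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata tibble.
#' @export
write_session_container <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dplyr::bind_rows(lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    file <- sprintf("trial%03d.tsv", i)
    readr::write_tsv(
      tibble::tibble(t = trace_time(tr), vm = tr$samples),
      file.path(dir, file))
    tibble::tibble(
      trial = i, file = file, fly_id = tr$fly_id, neuron_id = tr$neuron_id,
      direction = tr$trial$direction, condition = tr$trial$condition,
      seed = tr$seed, fs = tr$fs)
  }))
  jsonlite::write_json(meta, file.path(dir, "trials.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(meta)
}

#' Read a session container written by [write_session_container()]
#'
#' @param dir Container directory.
#' @return List of `voltage_trace` objects in trial order.
#' @export
read_session_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "trials.json"),
                              simplifyVector = TRUE)
  lapply(seq_len(nrow(meta)), function(i) {
    d <- readr::read_tsv(file.path(dir, meta$file[i]),
                         show_col_types = FALSE)
    structure(
      list(samples = d$vm, fs = meta$fs[i],
           trial = trial_spec(meta$direction[i], meta$condition[i]),
           spikes = NULL, neuron_id = meta$neuron_id[i],
           fly_id = meta$fly_id[i], seed = meta$seed[i]),
      class = "voltage_trace")
  })
}

#' Write a behavior record as delimited text plus a JSON sidecar
#'
#' The sample table (`t`, `dwba`, `orientation`, `airflow_on`, `in_slip`,
#' `trial`, `trial_type`) goes to `path`; arena, agent, schedule and
#' session metadata go to `<path>.json`.
#'
#' @param record A `behavior_record`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_behavior_record <- function(record, path) {
  readr::write_tsv(record$data, path)
  side <- list(
    arena = unclass(record$arena),
    agent = unclass(record$agent),
    schedule = as.data.frame(record$schedule),
    trial_len = attr(record$schedule, "trial_len"),
    reps_per_type = attr(record$schedule, "reps_per_type"),
    orientation0 = record$orientation0, fly_id = record$fly_id,
    genotype_label = record$genotype_label, seed = record$seed)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a behavior record, validating closed-loop consistency
#'
#' Rebuilds the record from the TSV + JSON sidecar and checks that the
#' stored orientation series is reproduced by re-integrating dWBA through
#' the arena update rule and schedule (to text round-trip precision).
#'
#' @param path TSV path written by [write_behavior_record()].
#' @param tol Maximum tolerated orientation discrepancy, degrees.
#' @return A `behavior_record`.
#' @export
read_behavior_record <- function(path, tol = 1e-6) {
  data <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- tibble::as_tibble(side$schedule)
  sched$duration_s <- as.numeric(sched$duration_s)
  sched$n_samples <- as.numeric(sched$n_samples)
  sched$sign <- as.numeric(sched$sign)
  attr(sched, "trial_len") <- side$trial_len
  attr(sched, "reps_per_type") <- side$reps_per_type
  class(sched) <- c("perturbation_schedule", class(sched))
  record <- structure(
    list(data = data, schedule = sched,
         arena = structure(side$arena, class = "arena_config"),
         agent = structure(side$agent, class = "fly_agent"),
         orientation0 = side$orientation0, fly_id = side$fly_id,
         genotype_label = side$genotype_label, seed = side$seed),
    class = "behavior_record")
  err <- max(abs(reconstruct_orientation(record) - data$orientation))
  if (err > tol)
    stop("closed-loop consistency violated on load (max error ",
         format(err), " deg)")
  record
}

#' Write / read a two-channel imaging series as delimited text
#'
#' Columns `t`, `green`, `red`, `direction`, `trial_id`.
#'
#' @param series A `two_channel_series`.
#' @param path Output TSV path.
#' @param trial_id Identifier stored with each row.
#' @return Invisibly, `path`.
#' @export
write_two_channel <- function(series, path, trial_id = 1) {
  readr::write_tsv(
    tibble::tibble(t = series$time, green = series$green, red = series$red,
                   direction = series$direction, trial_id = trial_id),
    path)
  invisible(path)
}

#' @rdname write_two_channel
#' @return `read_two_channel()` returns a `two_channel_series`.
#' @export
read_two_channel <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(time = d$t, green = d$green, red = d$red,
         direction = d$direction[1], fs = 1 / diff(d$t)[1],
         epochs = imaging_epochs(), seed = NA, response = NULL),
    class = "two_channel_series")
}
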