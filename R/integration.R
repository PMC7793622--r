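#' Predicted-vs-observed summation points
#'
#' For each stimulus direction, compares the mean multisensory response with
#' the sum of the mean single-modality responses. Points on the diagonal
#' indicate linear summation of modalities; systematic departures indicate
#' dominance of one modality. The trimodal variant compares the
#' stripe+airflow+odor response with mean(stripe) + mean(airflow+odor).
#'
#' @param responses Tidy per-trial (or per-cell mean) response table with
#'   columns `direction`, `condition`, `response`.
#' @param trimodal If `TRUE`, use the three-modality comparison.
#' @return Tibble with `direction`, `predicted`, `observed`.
#' @export
summation_points <- function(responses, trimodal = FALSE) {
  multi <- if (trimodal) "stripe+airflow+odor" else "stripe+airflow"
  uni_air <- if (trimodal) "airflow+odor" else "airflow"
  need <- c("stripe", uni_air, multi)
  means <- responses |>
    dplyr::filter(.data$condition %in% need) |>
    dplyr::group_by(.data$direction, .data$condition) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "response")
  if (!all(need %in% names(means)) || anyNA(means[need]))
    stop("all of ", paste(need, collapse = ", "),
         " must be present for every direction")
  tibble::tibble(
    direction = means$direction,
    predicted = means$stripe + means[[uni_air]],
    observed = means[[multi]])
}

#' Mean PSTHs per condition and direction
#'
#' Convenience builder for the similarity analysis: averages spike trains
#' within each (condition, direction) cell into one PSTH and returns a long
#' tidy table.
#'
#' @param trials Tibble with columns `direction`, `condition` and a
#'   list-column `spikes` of spike-time vectors.
#' @param ... Passed to [psth()] (kernel width, trial support, output rate).
#' @return Tibble: `condition`, `direction`, `time`, `rate`.
#' @export
condition_psths <- function(trials, ...) {
  stopifnot(all(c("direction", "condition", "spikes") %in% names(trials)))
  cells <- dplyr::distinct(trials[, c("condition", "direction")])
  dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$condition == cells$condition[i] &
      trials$direction == cells$direction[i]
    p <- psth(trials$spikes[sel], ...)
    tibble::tibble(condition = cells$condition[i],
                   direction = cells$direction[i],
                   time = p$time, rate = p$rate)
  }))
}

#' Cross-condition similarity coefficients (rho_a, rho_s)
#'
#' Quantifies whether a cell's multisensory response resembles its airflow
#' response, its stripe response, or both equally. Per-direction mean PSTHs
#' are baseline-subtracted, truncated to the stimulus-response and offset
#' periods (seconds 4-12 of the 12 s trial), concatenated over directions in
#' a fixed order, and correlated point-by-point: `rho_air` is the Pearson
#' correlation of the multisensory timecourse with the airflow-alone
#' timecourse, `rho_stripe` with the stripe-alone timecourse. Equal
#' coefficients are the hallmark of summation; one large and one small
#' coefficient indicates dominance of a single modality.
#'
#' @param psths Long tibble from [condition_psths()] (columns `condition`,
#'   `direction`, `time`, `rate`) containing at least the `multi`, `air` and
#'   `stripe` conditions for every direction in `dir_order`.
#' @param dir_order Direction concatenation order, degrees.
#' @param window Truncation window within the trial, seconds.
#' @param baseline_window Window whose mean is subtracted from each PSTH
#'   before truncation; `NULL` skips subtraction.
#' @param multi,air,stripe Condition labels.
#' @return A `similarity_result`: `rho_air`, `rho_stripe`, `n_points`,
#'   `degenerate` (`TRUE` when a concatenated series has zero variance, in
#'   which case the corresponding rho is `NA`, never silently 0).
#' @export
similarity_coefficients <- function(psths, dir_order = c(-90, 0, 90, 180),
                                    window = c(4, 12),
                                    baseline_window = c(2.5, 3.5),
                                    multi = "stripe+airflow",
                                    air = "airflow", stripe = "stripe") {
  concat <- function(cond) {
    out <- lapply(dir_order, function(d) {
      seg <- psths[psths$condition == cond & psths$direction == d, ]
      if (nrow(seg) == 0)
        stop("missing PSTH for condition ", cond, ", direction ", d)
      seg <- seg[order(seg$time), ]
      r <- seg$rate
      if (!is.null(baseline_window)) {
        b <- seg$time >= baseline_window[1] & seg$time < baseline_window[2]
        r <- r - mean(r[b])
      }
      r[seg$time >= window[1] & seg$time < window[2]]
    })
    lens <- lengths(out)
    if (length(unique(lens)) != 1) stop("PSTH segments differ in length")
    unlist(out)
  }
  m <- concat(multi)
  a <- concat(air)
  s <- concat(stripe)
  degen <- c(multi = sd(m) == 0, air = sd(a) == 0, stripe = sd(s) == 0)
  rho_air <- if (degen["multi"] || degen["air"]) NA_real_ else cor(m, a)
  rho_stripe <- if (degen["multi"] || degen["stripe"]) NA_real_ else cor(m, s)
  structure(
    list(rho_air = rho_air, rho_stripe = rho_stripe, n_points = length(m),
         degenerate = any(degen), degenerate_conditions = names(degen)[degen]),
    class = "similarity_result")
}
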