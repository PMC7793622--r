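#' Wrap angles to the fly-centered convention
#'
#' Angles are measured in degrees in a fly-centered frame: 0 is front,
#' +90 ipsilateral, 180 rear, -90 contralateral. All angles in the package
#' live on the half-open interval (-180, 180].
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped to (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps 180 -> -180; push it back to the closed end of (-180, 180]
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and resultant length of a set of angles
#'
#' Unit-vector average: each sample contributes a unit vector at its angle.
#' The resultant length is 1 when all samples coincide and tends to 0 for a
#' uniform distribution (it is one minus the circular variance).
#'
#' @param theta Angles in degrees.
#' @param w Optional weights (may be negative; see [mean_vector()]).
#' @return List with `angle` (degrees, `NA` if the resultant is null) and
#'   `length` (non-negative).
#' @export
circ_mean <- function(theta, w = NULL) {
  th <- deg2rad(theta)
  if (is.null(w)) w <- rep(1, length(th))
  x <- sum(w * cos(th))
  y <- sum(w * sin(th))
  r <- sqrt(x^2 + y^2)
  ang <- if (r < .Machine$double.eps^0.5 * max(1, sum(abs(w)))) NA_real_ else
    wrap_angle(rad2deg(atan2(y, x)))
  list(angle = ang, length = r)
}

#' Circular-Gaussian (von Mises shaped) directional tuning
#'
#' Tuning profile used by all synthetic generators: a von-Mises-shaped bump
#' `exp(kappa * (cos(delta) - 1))` with peak 1 at `pref_dir`, where `kappa`
#' is parameterized by the half-width at half-maximum in degrees. An optional
#' `inhib` term shifts the profile down (rescaled so the peak stays at 1), so
#' that anti-preferred directions drive negative values: this emulates the
#' active inhibition these neurons show for contralateral airflow.
#'
#' @param direction Stimulus direction(s), degrees.
#' @param pref_dir Preferred direction, degrees.
#' @param width Half-width at half-maximum, degrees (> 0).
#' @param inhib Depth of the subtractive floor in `[0, 1)`; 0 keeps the
#'   profile non-negative.
#' @return Tuning values with maximum 1 at `pref_dir`.
#' @export
#' @examples
#' tuning_shape(c(45, 225), pref_dir = 45, width = 60, inhib = 0.2)
tuning_shape <- function(direction, pref_dir, width, inhib = 0) {
  stopifnot(width > 0, inhib >= 0, inhib < 1)
  delta <- deg2rad(direction - pref_dir)
  kappa <- log(2) / (1 - cos(deg2rad(width)))
  f <- exp(kappa * (cos(delta) - 1))
  (f - inhib) / (1 - inhib)
}
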