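# Incident-field representations: analytic Gaussian-enveloped sinusoid or
# a field tabulated by points, plus the incident fluence.

#' Gaussian-enveloped sinusoidal pulse
#'
#' The incident field is
#' `eps(t) = eps0 * exp(-(t - t0)^2 / (2 sigma^2)) * cos(omega * (t - t0) + phase) * pol`
#' with the carrier phase referenced to the envelope centre `t0` (peak field
#' at the centre for `phase = 0`).
#'
#' @param eps0 peak field amplitude; atomic units by default, V/m with
#'   `amplitude_unit = "V/m"` (1 a.u. = 5.142e11 V/m).
#' @param sigma envelope width (fs).
#' @param t0 envelope centre (fs).
#' @param omega carrier frequency (eV by default, a.u. with
#'   `omega_unit = "au"`).
#' @param polarization unit 3-vector (normalized internally).
#' @param phase carrier phase at `t0` (radians).
#' @param amplitude_unit,omega_unit input units.
#' @return An object of class `gaussian_pulse` (all fields atomic units).
#' @export
gaussian_pulse <- function(eps0, sigma, t0, omega,
                           polarization = c(1, 0, 0), phase = 0,
                           amplitude_unit = c("au", "V/m"),
                           omega_unit = c("eV", "au")) {
  amplitude_unit <- match.arg(amplitude_unit)
  omega_unit <- match.arg(omega_unit)
  if (amplitude_unit == "V/m") eps0 <- vm_to_au(eps0)
  if (omega_unit == "eV") omega <- ev_to_au(omega)
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_pulse: sigma must be > 0")
  if (eps0 < 0) stop("gaussian_pulse: amplitude must be >= 0")
  pol <- as.numeric(polarization)
  if (length(pol) != 3L || all(pol == 0)) stop("gaussian_pulse: bad polarization")
  pol <- pol / sqrt(sum(pol^2))
  structure(list(eps0 = eps0, sigma = fs_to_au(sigma), t0 = fs_to_au(t0),
                 omega = omega, phase = phase, pol = pol),
            class = c("gaussian_pulse", "pulse"))
}

#' Pulse tabulated by points
#'
#' A field known only by points on a strictly increasing time grid, linearly
#' interpolated between nodes and zero outside the grid.
#'
#' @param time time nodes (fs).
#' @param field field value per node (a.u. by default, `"V/m"` accepted).
#' @param polarization unit 3-vector.
#' @param amplitude_unit input unit of `field`.
#' @return An object of class `tabulated_pulse`.
#' @export
tabulated_pulse <- function(time, field, polarization = c(1, 0, 0),
                            amplitude_unit = c("au", "V/m")) {
  amplitude_unit <- match.arg(amplitude_unit)
  if (amplitude_unit == "V/m") field <- vm_to_au(field)
  if (length(time) != length(field) || length(time) < 2L)
    stop("tabulated_pulse: time and field must be equal length >= 2")
  if (any(diff(time) <= 0))
    stop("tabulated_pulse: time grid must be strictly increasing")
  if (any(!is.finite(field))) stop("tabulated_pulse: field must be finite")
  pol <- as.numeric(polarization)
  if (length(pol) != 3L || all(pol == 0)) stop("tabulated_pulse: bad polarization")
  pol <- pol / sqrt(sum(pol^2))
  structure(list(time = fs_to_au(time), field = field, pol = pol),
            class = c("tabulated_pulse", "pulse"))
}

#' Scalar field amplitude at given times (atomic units)
#'
#' The field along its polarization direction; [field_at()] returns the full
#' 3-vector(s).
#'
#' @param pulse a pulse object.
#' @param t time(s), atomic units.
#' @return numeric vector of field values (a.u.).
#' @export
field_scalar <- function(pulse, t) UseMethod("field_scalar")

#' @export
field_scalar.gaussian_pulse <- function(pulse, t) {
  u <- t - pulse$t0
  pulse$eps0 * exp(-u^2 / (2 * pulse$sigma^2)) * cos(pulse$omega * u + pulse$phase)
}

#' @export
field_scalar.tabulated_pulse <- function(pulse, t) {
  out <- numeric(length(t))
  inside <- t >= pulse$time[1] & t <= pulse$time[length(pulse$time)]
  if (any(inside))
    out[inside] <- stats::approx(pulse$time, pulse$field, xout = t[inside])$y
  out
}

#' Incident field vector at a time
#'
#' @param pulse a pulse object.
#' @param t a single time (atomic units).
#' @return field 3-vector in atomic units (zero vector outside a tabulated
#'   pulse's grid).
#' @export
field_at <- function(pulse, t) {
  stopifnot(is.finite(t))
  field_scalar(pulse, t) * pulse$pol
}

#' Time integral of the squared field
#'
#' `int eps(t)^2 dt` in atomic units; for a Gaussian pulse with
#' `omega * sigma >> 1` this equals `eps0^2 * sigma * sqrt(pi) / 2`.
#' Evaluated in closed form for the Gaussian pulse (including the
#' finite-bandwidth carrier correction) and by the trapezoidal rule on a
#' fine grid for tabulated pulses.
#'
#' @param pulse a pulse object.
#' @export
field_squared_integral <- function(pulse) UseMethod("field_squared_integral")

#' @export
field_squared_integral.gaussian_pulse <- function(pulse) {
  # int g^2 cos^2 = (sigma sqrt(pi)/2) (1 + cos(2 phase) exp(-sigma^2 omega^2))
  pulse$eps0^2 * pulse$sigma * sqrt(pi) / 2 *
    (1 + cos(2 * pulse$phase) * exp(-pulse$sigma^2 * pulse$omega^2))
}

#' @export
field_squared_integral.tabulated_pulse <- function(pulse) {
  if (any(!is.finite(pulse$field)))
    stop("field_squared_integral: non-normalizable tabulated pulse")
  tt <- pulse$time
  ff <- pulse$field^2
  sum(diff(tt) * (ff[-1] + ff[-length(ff)]) / 2)
}

#' Fluence of the incident pulse
#'
#' Time-integrated energy per unit area, `F = (c / 4 pi) int eps(t)^2 dt`
#' in atomic units (Gaussian electromagnetic conventions: the instantaneous
#' Poynting flux of a plane wave is `c E^2 / 4 pi`, and the carrier's
#' `cos^2` already averages to 1/2 inside the time integral).  This is the
#' denominator of the cumulative cross-section;
#' its prefactor is chosen consistently with the scattered-energy prefactor
#' of [cross_section()] so that the quasi-CW limit reproduces the
#' Kramers-Heisenberg-Dirac differential cross-section.
#'
#' @param pulse a pulse object.
#' @return fluence in atomic units (energy / area).
#' @export
fluence <- function(pulse) {
  au$c_au / (4 * pi) * field_squared_integral(pulse)
}

#' Replace the polarization direction of a pulse
#'
#' @param pulse a pulse object.
#' @param pol new polarization 3-vector (normalized internally).
#' @export
with_polarization <- function(pulse, pol) {
  pol <- as.numeric(pol)
  if (length(pol) != 3L || all(pol == 0)) stop("with_polarization: bad vector")
  pulse$pol <- pol / sqrt(sum(pol^2))
  pulse
}

#' @export
print.gaussian_pulse <- function(x, ...) {
  cat(sprintf(
    "<gaussian_pulse> eps0 %.3g a.u., sigma %.1f fs, t0 %.1f fs, omega %.3f eV\n",
    x$eps0, au_to_fs(x$sigma), au_to_fs(x$t0), x$omega * au$hartree_eV))
  invisible(x)
}

#' @export
print.tabulated_pulse <- function(x, ...) {
  cat(sprintf("<tabulated_pulse> %d nodes, %.1f..%.1f fs\n",
              length(x$time), au_to_fs(x$time[1]),
              au_to_fs(x$time[length(x$time)])))
  invisible(x)
}
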