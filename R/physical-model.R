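#' Construct an imaging beam geometry
#'
#' Builds the monochromatic parallel/quasi-spherical beam description used by
#' the simulator and the metrics: wavelength, wavenumber, photon energy,
#' geometric magnification `M = (R1 + R2)/R1` and effective propagation
#' distance `R' = R2/M`. All internally stored lengths are in metres and
#' energies in joules; the constructor accepts keV at the boundary.
#'
#' @param energy Photon energy in keV (scalar, > 0).
#' @param r1 Source-to-sample distance in metres (> 0).
#' @param r2 Sample-to-detector distance in metres (>= 0).
#' @return An object of class `pbct_beam`: a list with fields `energy_kev`,
#'   `photon_energy` (J), `wavelength` (m), `wavenumber` (1/m), `r1`, `r2`,
#'   `magnification` and `effective_distance` (m).
#' @examples
#' b <- make_beam(32, 138, 5)
#' b$wavelength * 1e10   # ~0.3875 Angstrom
#' b$effective_distance  # ~4.83 m
#' @export
make_beam <- function(energy, r1, r2) {
  if (!is.numeric(energy) || length(energy) != 1 || !is.finite(energy) ||
      energy <= 0)
    stop_invalid("`energy` must be a single positive number (keV)")
  if (!is.numeric(r1) || length(r1) != 1 || r1 <= 0)
    stop_invalid("`r1` must be a single positive distance (m)")
  if (!is.numeric(r2) || length(r2) != 1 || r2 < 0)
    stop_invalid("`r2` must be a single non-negative distance (m)")
  e_ph <- energy * 1e3 * .const$e
  lambda <- .const$h * .const$c / e_ph
  m <- (r1 + r2) / r1
  structure(list(
    energy_kev = energy,
    photon_energy = e_ph,
    wavelength = lambda,
    wavenumber = 2 * pi / lambda,
    r1 = r1,
    r2 = r2,
    magnification = m,
    effective_distance = r2 / m
  ), class = "pbct_beam")
}

#' @export
print.pbct_beam <- function(x, ...) {
  cat(sprintf(
    "<pbct_beam> %.4g keV (lambda = %.4g A), R1 = %g m, R2 = %g m, M = %.4f, R' = %.4f m\n",
    x$energy_kev, x$wavelength * 1e10, x$r1, x$r2, x$magnification,
    x$effective_distance))
  invisible(x)
}

#' Optical material properties from beta and gamma
#'
#' Completes the complex-refractive-index description of a monomorphous
#' material, `n = 1 - delta + i*beta`, from the imaginary part `beta` and the
#' fixed ratio `gamma = delta/beta`, including the linear attenuation
#' coefficient `mu = 4*pi*beta/lambda`.
#'
#' @param beta Imaginary refractive-index part (dimensionless, >= 0).
#' @param gamma Ratio delta/beta (dimensionless, >= 0).
#' @param wavelength X-ray wavelength in metres, or a [make_beam()] object.
#' @param mu_en_rho Optional mass energy-absorption coefficient (m^2/kg).
#' @param density Optional mass density (kg/m^3).
#' @return An object of class `pbct_material` with fields `delta`, `beta`,
#'   `gamma`, `mu` (1/m), `mu_en_rho` and `density`.
#' @examples
#' b <- make_beam(32, 138, 5)
#' material_from_beta(1e-10, 869.4, b)$delta
#' @export
material_from_beta <- function(beta, gamma, wavelength,
                               mu_en_rho = NA_real_, density = NA_real_) {
  if (inherits(wavelength, "pbct_beam")) wavelength <- wavelength$wavelength
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0)
    stop_invalid("`beta` must be a single non-negative number")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    stop_invalid("`gamma` must be a single non-negative number")
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop_invalid("`wavelength` must be a single positive length (m)")
  structure(list(
    delta = gamma * beta,
    beta = beta,
    gamma = gamma,
    mu = 4 * pi * beta / wavelength,
    mu_en_rho = mu_en_rho,
    density = density
  ), class = "pbct_material")
}

#' Construct a detector model
#'
#' Describes the detector by its pixel pitch, point-spread-function shape and
#' width, zero-frequency detective quantum efficiency `kappa = DQE(0)`, and
#' noise mode. The resolution `res` is defined as twice the PSF standard
#' deviation, measured in the detector plane.
#'
#' For `mode = "photon_counting"` the simulator applies Poisson noise per
#' pixel after the PSF blur, so flat-field counts obey variance/mean = 1. For
#' `mode = "energy_integrating"` (scintillator-coupled) Poisson noise acts at
#' the photon-absorption stage, before the optical PSF blur, producing
#' PSF-correlated noise.
#'
#' @param pixel_pitch Pixel pitch in micrometres (> 0).
#' @param res PSF resolution `Res = 2*sigma` in micrometres (> 0).
#' @param psf_shape `"gaussian"` or `"rect"`.
#' @param kappa DQE(0), in (0, 1].
#' @param mode `"photon_counting"` or `"energy_integrating"`.
#' @return An object of class `pbct_detector`.
#' @examples
#' make_detector(75, 86.2, "rect", 1, "photon_counting")
#' @export
make_detector <- function(pixel_pitch, res,
                          psf_shape = c("gaussian", "rect"),
                          kappa = 1,
                          mode = c("photon_counting", "energy_integrating")) {
  psf_shape <- match.arg(psf_shape)
  mode <- match.arg(mode)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 || pixel_pitch <= 0)
    stop_invalid("`pixel_pitch` must be a single positive number (um)")
  if (!is.numeric(res) || length(res) != 1 || res <= 0)
    stop_invalid("`res` must be a single positive number (um)")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0 || kappa > 1)
    stop_invalid("`kappa` must lie in (0, 1]")
  structure(list(
    pixel_pitch = pixel_pitch,
    res = res,
    sigma = res / 2,
    psf_shape = psf_shape,
    kappa = kappa,
    mode = mode
  ), class = "pbct_detector")
}

#' @export
print.pbct_detector <- function(x, ...) {
  cat(sprintf(
    "<pbct_detector> pitch %g um, %s PSF Res = %g um, kappa = %g, %s\n",
    x$pixel_pitch, x$psf_shape, x$res, x$kappa, x$mode))
  invisible(x)
}
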