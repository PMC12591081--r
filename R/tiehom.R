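#' TIE-Hom regularisation parameter
#'
#' Computes the length parameter of the homogeneous transport-of-intensity
#' (TIE-Hom) operators, `a = sqrt(gamma * R' * lambda / (4*pi))`, from the
#' material ratio gamma and a beam geometry.
#'
#' @param gamma Ratio delta/beta (>= 0).
#' @param beam A [make_beam()] object, or a list with `effective_distance`
#'   and `wavelength` in metres.
#' @return Object of class `pbct_tieparams`: list with `a` (m), `gamma`,
#'   `effective_distance` (m) and `wavelength` (m).
#' @examples
#' p <- tie_param(869.4, make_beam(32, 138, 5))
#' p$a * 1e6  # ~113.8 um
#' @export
tie_param <- function(gamma, beam) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    stop_invalid("`gamma` must be a single non-negative number")
  rp <- beam$effective_distance
  lambda <- beam$wavelength
  structure(list(
    a = sqrt(gamma * rp * lambda / (4 * pi)),
    gamma = gamma,
    effective_distance = rp,
    wavelength = lambda
  ), class = "pbct_tieparams")
}

# Shared implementation of the four Fourier TIE-Hom operators.
# direction: +1 forward (1 + 4 pi^2 a^2 rho^2), -1 inverse (reciprocal).
#' @noRd
tiehom_filter <- function(x, p, pixel, direction, pad) {
  if (!is.numeric(pixel) || length(pixel) != 1 || pixel <= 0)
    stop_invalid("`pixel` must be a single positive sample size (um)")
  a <- p$a
  if (a == 0) return(x)
  d <- pixel * .um
  nd <- length(dim(x))
  n <- dim(x)
  if (a >= min(n) * d / 2)
    stop_invalid("ill-conditioned TIE-Hom filter: a = ", signif(a, 4),
                 " m is comparable to the field size ", signif(min(n) * d, 4),
                 " m")
  np <- if (pad) min(ceiling(8 * a / d), min(n)) else 0L
  xp <- if (nd == 2) pad_mirror_2d(x, np) else pad_mirror_3d(x, np)
  r2 <- if (nd == 2) freq_rho2_2d(dim(xp), d) else freq_rho2_3d(dim(xp), d)
  h <- 1 + 4 * pi^2 * a^2 * r2
  if (direction < 0) h <- 1 / h
  out <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / length(xp)
  if (np > 0) {
    out <- if (nd == 2) crop_2d(out, np, n) else crop_3d(out, np, n)
  }
  out
}

#' TIE-Hom forward operator (2D)
#'
#' Applies `(1 - a^2 * Laplacian)` to a contact-plane fluence image,
#' producing the free-space-propagated fluence of a monomorphous object in
#' the TIE-Hom approximation. Implemented as Fourier multiplication by
#' `1 + 4*pi^2*a^2*rho^2` (e^(-2*pi*i) transform convention), which preserves
#' the image mean exactly. Non-periodic images are mirror-padded by at least
#' `8a` before filtering and cropped back.
#'
#' @param i0 Contact fluence image (numeric matrix, strictly positive for a
#'   physical fluence).
#' @param p A [tie_param()] object.
#' @param pixel Sample spacing of `i0` in micrometres (object plane).
#' @param pad Mirror-pad before filtering (default `TRUE`).
#' @return Matrix of the same dimensions as `i0`.
#' @examples
#' p <- tie_param(869.4, make_beam(32, 138, 5))
#' img <- matrix(1, 64, 64)
#' range(tie_forward_2d(img, p, pixel = 100) - 1)  # constant is unchanged
#' @export
tie_forward_2d <- function(i0, p, pixel, pad = TRUE) {
  if (!is.matrix(i0)) stop_invalid("`i0` must be a numeric matrix")
  tiehom_filter(i0, p, pixel, direction = +1, pad = pad)
}

#' TIE-Hom inverse operator (2D phase retrieval)
#'
#' Single-distance phase-retrieval filter for monomorphous objects: Fourier
#' multiplication by `1 / (1 + 4*pi^2*a^2*rho^2)`. Exact inverse of
#' [tie_forward_2d()] on periodic grids; unconditionally stable; preserves
#' the image mean.
#'
#' @inheritParams tie_forward_2d
#' @param i_r Propagated fluence image (numeric matrix).
#' @return Matrix of the same dimensions as `i_r`.
#' @export
tie_inverse_2d <- function(i_r, p, pixel, pad = TRUE) {
  if (!is.matrix(i_r)) stop_invalid("`i_r` must be a numeric matrix")
  tiehom_filter(i_r, p, pixel, direction = -1, pad = pad)
}

#' TIE-Hom inverse operator (3D)
#'
#' Three-dimensional counterpart of [tie_inverse_2d()], applied to a
#' reconstructed volume with the 3D radial frequency. Equivalent to
#' convolution with the Yukawa (screened-Coulomb) kernel of
#' [kernel_yukawa()].
#'
#' @param volume Numeric 3D array.
#' @param p A [tie_param()] object.
#' @param voxel Isotropic voxel size in micrometres.
#' @param pad Mirror-pad before filtering (default `TRUE`).
#' @return Array of the same dimensions as `volume`.
#' @export
tie_inverse_3d <- function(volume, p, voxel, pad = TRUE) {
  if (!is.array(volume) || length(dim(volume)) != 3)
    stop_invalid("`volume` must be a 3D numeric array")
  tiehom_filter(volume, p, voxel, direction = -1, pad = pad)
}

#' Real-space kernel of the 2D TIE-Hom inverse operator
#'
#' Samples the K0 (modified Bessel, second kind) kernel
#' `K0(r/a) / (2*pi*a^2)` on a square grid, truncated at radius `12a` and
#' renormalised to unit sum so that convolution preserves the image mean.
#' The diverging central sample is replaced by its exact cell average over an
#' equivalent-area disc. The attribute `raw_integral` stores the discrete
#' integral before renormalisation.
#'
#' @param p A [tie_param()] object with `a > 0` (for `a = 0` a delta kernel
#'   is returned).
#' @param pixel Grid spacing in micrometres.
#' @return Square numeric matrix of odd side, summing to 1.
#' @export
kernel_k0 <- function(p, pixel) {
  d <- pixel * .um
  a <- p$a
  if (a == 0) return(matrix(1, 1, 1))
  m <- ceiling(12 * a / d)
  x <- seq(-m, m) * d
  r <- sqrt(outer(x^2, x^2, `+`))
  k <- matrix(0, nrow = length(x), ncol = length(x))
  inside <- r <= 12 * a
  k[inside] <- besselK(r[inside] / a, 0) / (2 * pi * a^2) * d^2
  # near the core the kernel varies steeply within a cell: replace point
  # samples by 7x7 cell averages there so the discrete integral is accurate
  core <- which(inside & r > 0 & r < 6 * a, arr.ind = TRUE)
  if (nrow(core) > 0) {
    sub <- function(n) (seq_len(n) - (n + 1) / 2) / n * d
    for (i in seq_len(nrow(core))) {
      s <- sub(if (r[core[i, 1], core[i, 2]] < 2 * a) 11L else 5L)
      rs <- sqrt(outer((x[core[i, 1]] + s)^2, (x[core[i, 2]] + s)^2, `+`))
      k[core[i, 1], core[i, 2]] <-
        mean(besselK(rs / a, 0)) / (2 * pi * a^2) * d^2
    }
  }
  # central cell: integral of the kernel over a disc of equal area,
  # int_0^R K0(r/a) r dr / a^2 = 1 - (R/a) K1(R/a)
  req <- d / sqrt(pi)
  k[m + 1, m + 1] <- 1 - (req / a) * besselK(req / a, 1)
  attr(k, "raw_integral") <- sum(k)
  k <- k / sum(k)
  attr(k, "pixel") <- pixel
  k
}

#' Real-space kernel of the 3D TIE-Hom inverse operator
#'
#' Samples the Yukawa (screened Coulomb) kernel
#' `exp(-r/a) / (4*pi*a^2*r)` on a cubic grid, truncated at radius `12a` and
#' renormalised to unit sum. The central sample uses the exact integral over
#' an equivalent-volume sphere.
#'
#' @inheritParams kernel_k0
#' @param voxel Grid spacing in micrometres.
#' @return Cubic numeric array of odd side, summing to 1, with attribute
#'   `raw_integral`.
#' @export
kernel_yukawa <- function(p, voxel) {
  d <- voxel * .um
  a <- p$a
  if (a == 0) return(array(1, c(1, 1, 1)))
  m <- ceiling(12 * a / d)
  x <- seq(-m, m) * d
  n1 <- length(x)
  r <- sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
  k <- array(0, dim(r))
  inside <- r <= 12 * a & r > 0
  k[inside] <- exp(-r[inside] / a) / (4 * pi * a^2 * r[inside]) * d^3
  # cell-average the steep core (1/r singularity) with subsamples
  core <- which(inside & r < 6 * a, arr.ind = TRUE)
  if (nrow(core) > 0) {
    sub <- function(n) (seq_len(n) - (n + 1) / 2) / n * d
    for (i in seq_len(nrow(core))) {
      s <- sub(if (r[core[i, 1], core[i, 2], core[i, 3]] < 2 * a) 9L else 3L)
      rs <- sqrt(outer(outer((x[core[i, 1]] + s)^2, (x[core[i, 2]] + s)^2,
                             `+`), (x[core[i, 3]] + s)^2, `+`))
      k[core[i, 1], core[i, 2], core[i, 3]] <-
        mean(exp(-rs / a) / (4 * pi * a^2 * rs)) * d^3
    }
  }
  # central cell: int over sphere of equal volume,
  # (1/a^2) int_0^R exp(-r/a) r dr = 1 - exp(-R/a) (1 + R/a)
  req <- d * (3 / (4 * pi))^(1 / 3)
  ctr <- (n1 + 1) / 2
  k[ctr, ctr, ctr] <- 1 - exp(-req / a) * (1 + req / a)
  attr(k, "raw_integral") <- sum(k)
  k <- k / sum(k)
  attr(k, "voxel") <- voxel
  k
}

#' Angular-spectrum Fresnel propagator
#'
#' Propagates a complex scalar field by the paraxial (Fresnel) transfer
#' function `exp(-i*pi*lambda*R*rho^2)` evaluated in the Fourier domain
#' (e^(-2*pi*i) convention, constant global phase dropped). The propagator is
#' unitary: total fluence is conserved to numerical precision. Used as the
#' validation oracle for the TIE-Hom approximation.
#'
#' @param field Complex (or numeric) matrix of the field amplitude.
#' @param distance Propagation distance in metres (may be an effective
#'   distance).
#' @param wavelength Wavelength in metres.
#' @param pixel Sample spacing in micrometres.
#' @param check_sampling If `TRUE` (default), raise an error when more than
#'   1% of the spectral energy lies in the outermost 5% frequency band,
#'   indicating aliasing.
#' @return Complex matrix of the propagated field.
#' @export
fresnel_propagate <- function(field, distance, wavelength, pixel,
                              check_sampling = TRUE) {
  if (!is.matrix(field)) stop_invalid("`field` must be a matrix")
  if (distance < 0) stop_invalid("`distance` must be non-negative")
  if (distance == 0) return(field + 0i)
  d <- pixel * .um
  ft <- stats::fft(field)
  r2 <- freq_rho2_2d(dim(field), d)
  if (check_sampling) {
    nyq2 <- (0.5 / d)^2
    band <- r2 > (0.95^2) * nyq2
    frac <- sum(Mod(ft[band])^2) / sum(Mod(ft)^2)
    if (frac > 0.01)
      stop_invalid("sampling error: ", signif(100 * frac, 3),
                   "% of spectral energy in the outermost frequency band")
  }
  h <- exp(-1i * pi * wavelength * distance * r2)
  stats::fft(ft * h, inverse = TRUE) / length(field)
}

#' Monomorphous complex field from a contact fluence image
#'
#' Builds the complex amplitude `sqrt(I) * exp(i*phi)` of a monomorphous
#' object from its contact-plane fluence, with the phase tied to the
#' log-attenuation by `phi = (gamma/2) * log(I / i_in)`.
#'
#' @param i0 Contact fluence image (strictly positive matrix).
#' @param i_in Incident (flat-field) fluence level.
#' @param gamma Ratio delta/beta.
#' @return Complex matrix.
#' @export
monomorphous_field <- function(i0, i_in, gamma) {
  if (any(i0 <= 0)) stop_invalid("`i0` must be strictly positive")
  sqrt(i0) * exp(1i * (gamma / 2) * log(i0 / i_in))
}

#' Closed-form first-fringe contrast of a phase edge
#'
#' Near-Fresnel-regime estimate of the propagation-induced fringe contrast
#' `(max - min) / (max + min)` of a resolution-blurred phase step:
#' `C = (2 / sqrt(2*pi*e)) * phi0 / N_F`, where `phi0 = 2*pi*delta*thickness /
#' lambda` is the phase step height and `N_F = resolution^2 / (R_eff *
#' lambda)` the Fresnel number of the resolution element. Validated against
#' the [fresnel_propagate()] oracle (agreement within ~10% for `N_F >~ 1` and
#' weak contrast).
#'
#' @param delta Real refractive-index decrement of the step material.
#' @param wavelength Wavelength in metres.
#' @param r_eff Effective propagation distance in metres.
#' @param resolution Object-plane resolution width (deltabar) in micrometres.
#' @param thickness Projected thickness of the phase step in metres.
#' @return Scalar contrast in `[0, 1]`.
#' @export
edge_contrast <- function(delta, wavelength, r_eff, resolution, thickness) {
  if (delta < 0 || thickness < 0) stop_invalid("`delta` and `thickness` must be non-negative")
  if (r_eff < 0) stop_invalid("`r_eff` must be non-negative")
  if (delta == 0 || r_eff == 0 || thickness == 0) return(0)
  n_f <- (resolution * .um)^2 / (r_eff * wavelength)
  if (n_f < 1)
    stop_invalid("near-Fresnel validity condition violated: N_F = ",
                 signif(n_f, 4), " < 1")
  phi0 <- 2 * pi * delta * thickness / wavelength
  ctr <- (2 / sqrt(2 * pi * exp(1))) * phi0 / n_f
  if (ctr > 0.5)
    stop_invalid("weak-contrast validity condition violated: ",
                 "predicted contrast ", signif(ctr, 4), " > 0.5")
  ctr
}
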