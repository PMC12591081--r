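# Synthetic-data generator: two-tissue breast-like phantoms, flat fields and
# full noisy PB-CT scans with dose-consistent fluence.

#' Two-tissue cylindrical breast phantom
#'
#' Builds a voxelised cylinder of adipose-like background (imaginary
#' refractive-index part `beta_adipose`) containing non-overlapping
#' glandular-like spherical inclusions (`beta_glandular`). The cylinder axis
#' is y (the rotation axis of the scan geometry); `beta = 0` outside the
#' support. Deterministic for a fixed seed.
#'
#' @param r_c Support cylinder radius in metres.
#' @param height Support cylinder height in metres.
#' @param voxel Isotropic voxel size in micrometres.
#' @param beta_adipose,beta_glandular Tissue beta values (dimensionless).
#' @param n_inclusions Number of spherical inclusions (>= 0).
#' @param seed RNG seed for inclusion placement.
#' @param margin Fractional transverse margin around the cylinder
#'   (default 0.1), setting the grid field of view.
#' @return Object of class `pbct_phantom`: list with `beta` (`[nx, ny, nz]`
#'   array), `label` (integer array: 0 air, 1 adipose, 2 glandular), `voxel`
#'   (um), `r_c`, `height`, `beta_adipose`, `beta_glandular`, `seed`.
#' @examples
#' ph <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 2, seed = 1)
#' dim(ph$beta)
#' @export
make_breast_phantom <- function(r_c, height, voxel,
                                beta_adipose = 7.3e-11,
                                beta_glandular = 1.0e-10,
                                n_inclusions = 5, seed = 1,
                                margin = 0.1) {
  if (r_c <= 0 || height <= 0 || voxel <= 0)
    stop_invalid("`r_c`, `height` and `voxel` must be positive")
  d <- voxel * .um
  nx <- 2L * ceiling((1 + margin) * r_c / d)  # even transverse size (diameter)
  nz <- nx
  ny <- max(1L, as.integer(round(height / d)))
  cx <- (nx + 1) / 2
  x <- (seq_len(nx) - cx) * d
  r2 <- outer(x^2, x^2, `+`)
  inside <- r2 <= r_c^2
  label_slice <- matrix(0L, nx, nz)
  label_slice[inside] <- 1L
  label <- array(rep(label_slice, ny), c(nx, nz, ny))

  spheres <- NULL
  if (n_inclusions > 0) {
    spheres <- with_seed(seed, {
      placed <- matrix(numeric(0), ncol = 4)
      tries <- 0L
      while (nrow(placed) < n_inclusions) {
        tries <- tries + 1L
        if (tries > 2000L)
          stop_invalid("could not place ", n_inclusions,
                       " non-overlapping inclusions after bounded retries")
        rad <- stats::runif(1, 0.08, 0.15) * r_c
        rad <- max(rad, 1.5 * d)
        rho <- sqrt(stats::runif(1)) * (0.75 * r_c - rad)
        phi <- stats::runif(1, 0, 2 * pi)
        cxy <- c(rho * cos(phi), rho * sin(phi))
        cy <- stats::runif(1, -1, 1) * max(height / 2 - rad, 0)
        cand <- c(cxy, cy, rad)
        ok <- TRUE
        if (nrow(placed) > 0) {
          dist <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cand[1:3])^2))
          ok <- all(dist > placed[, 4] + rad)
        }
        if (ok) placed <- rbind(placed, cand)
      }
      placed
    })
    y <- (seq_len(ny) - (ny + 1) / 2) * d
    for (i in seq_len(nrow(spheres))) {
      s <- spheres[i, ]
      dx2 <- outer((x - s[1])^2, (x - s[2])^2, `+`)  # (x, z) plane
      for (j in seq_len(ny)) {
        dy2 <- (y[j] - s[3])^2
        label[, , j][dx2 + dy2 <= s[4]^2] <- 2L
      }
    }
  }
  label <- aperm(label, c(1, 3, 2))  # -> [nx, ny, nz]
  beta <- array(0, dim(label))
  beta[label == 1L] <- beta_adipose
  beta[label == 2L] <- beta_glandular
  structure(list(beta = beta, label = label, voxel = voxel, r_c = r_c,
                 height = height, beta_adipose = beta_adipose,
                 beta_glandular = beta_glandular, seed = seed,
                 inclusions = spheres),
            class = "pbct_phantom")
}

#' Air-kerma dose record
#'
#' Collects the dose bookkeeping of a scan: entrance air kerma, per-angle
#' incident fluence `I_in = K_air / (M_a * K_tr_air)`, and mean glandular
#' dose `D_g = c_D * K_air`. The kerma-to-MGD conversion factor `c_D` is a
#' required input (it is normally obtained from Monte Carlo dosimetry, which
#' is out of scope here).
#'
#' @param k_air Entrance air kerma in Gy.
#' @param m_a Number of view angles sharing the kerma budget.
#' @param energy Photon energy in keV (for [k_tr_air()]).
#' @param c_d Kerma-to-MGD conversion factor (dimensionless).
#' @param g Bremsstrahlung escape fraction in `[0, 1)` (default 0).
#' @return Object of class `pbct_dose`: list with `k_air` (Gy), `k_tr_air`
#'   (Gy m^2), `i_in_2d` (photons/um^2 per angle), `mgd` (Gy), `c_d`, `g`,
#'   `m_a`.
#' @examples
#' make_dose_record(8e-3, 600, 32, 0.5)$i_in_2d  # ~0.19 photons/um^2
#' @export
make_dose_record <- function(k_air, m_a, energy, c_d, g = 0) {
  if (k_air <= 0 || m_a < 1) stop_invalid("`k_air` must be > 0 and `m_a` >= 1")
  if (g < 0 || g >= 1) stop_invalid("`g` must lie in [0, 1)")
  ktr <- k_tr_air(energy)
  structure(list(
    k_air = k_air,
    k_tr_air = ktr,
    i_in_2d = k_air / (m_a * ktr) * .um^2,  # photons per um^2
    mgd = c_d * k_air,
    c_d = c_d,
    g = g,
    m_a = as.integer(m_a)
  ), class = "pbct_dose")
}

# Detector PSF as a discrete object-plane kernel (vector of per-axis kernels
# is unnecessary: blur is applied via FFT with the analytic transfer
# function for gaussian, or a sampled separable kernel for rect).
#' @noRd
detector_blur <- function(img, detector, pixel, magnification = 1) {
  if (detector$psf_shape == "gaussian") {
    sigma_px <- detector$sigma / magnification / pixel
    if (sigma_px < 1e-3) return(img)
    return(gauss_smooth_fft(img, sigma_px))
  }
  # rect PSF: separable boxcar of full width res/M in the object plane
  w_px <- detector$res / magnification / pixel
  if (w_px <= 1e-3) return(img)
  n <- dim(img)
  f1 <- fft_freq(n[1], 1); f2 <- fft_freq(n[2], 1)
  sinc <- function(f) ifelse(f == 0, 1, sin(pi * f * w_px) / (pi * f * w_px))
  h <- outer(sinc(f1), sinc(f2))
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / length(img)
}

# Apply the detector noise/blur chain to a noiseless fluence image.
#' @noRd
detect_frame <- function(i_det, detector, pixel, magnification, noisy) {
  area <- (pixel)^2                       # object-plane pixel area, um^2
  counts_mean <- i_det * area * detector$kappa
  if (!noisy) {
    counts <- detector_blur(counts_mean, detector, pixel, magnification)
  } else if (detector$mode == "energy_integrating") {
    counts <- matrix(stats::rpois(length(counts_mean), counts_mean),
                     nrow(counts_mean), ncol(counts_mean))
    counts <- detector_blur(counts, detector, pixel, magnification)
  } else {
    counts <- detector_blur(counts_mean, detector, pixel, magnification)
    counts <- matrix(stats::rpois(length(counts), pmax(counts, 0)),
                     nrow(counts), ncol(counts))
  }
  counts / (area * detector$kappa)        # back to fluence units
}

#' Simulate a detector flat field
#'
#' Produces one noisy flat-field frame: per-pixel Poisson counts with mean
#' `i_in * pixel_area * kappa` passed through the detector chain of
#' [make_detector()], rescaled back to fluence units.
#'
#' @param i_in Incident fluence in photons/um^2.
#' @param shape Integer vector `c(nx, ny)` of the frame size in pixels.
#' @param detector A [make_detector()] object.
#' @param seed RNG seed (optional).
#' @param magnification Geometric magnification mapping the detector PSF to
#'   the object plane (default 1; pixels are assumed given in the object
#'   plane when `magnification = 1`).
#' @param pixel Object-plane pixel size in micrometres (default
#'   `detector$pixel_pitch / magnification`).
#' @return Numeric matrix of fluence values (photons/um^2).
#' @export
simulate_flat_field <- function(i_in, shape, detector, seed = NULL,
                                magnification = 1,
                                pixel = detector$pixel_pitch / magnification) {
  if (i_in <= 0) stop_invalid("`i_in` must be positive")
  flat <- matrix(i_in, shape[1], shape[2])
  with_seed(seed, detect_frame(flat, detector, pixel, magnification,
                               noisy = TRUE))
}

#' Simulate a full PB-CT scan
#'
#' Generates an angle-indexed stack of detector fluence images of a phantom:
#' X-ray projection of beta, Beer-Lambert attenuation
#' `I = I_in * exp(-4*pi/lambda * integral(beta))`, optional TIE-Hom forward
#' propagation to the effective distance (`distance_tag = "R"`), detector
#' PSF blur and Poisson noise with efficiency kappa (noise before the blur
#' for energy-integrating detectors, after it for photon counting). A flat
#' field is simulated with the identical chain minus the phantom.
#'
#' The object-plane sampling is the detector pitch divided by the
#' magnification and must match the phantom voxel size.
#'
#' @param phantom A [make_breast_phantom()] object (or compatible list).
#' @param beam A [make_beam()] object.
#' @param detector A [make_detector()] object.
#' @param dose A [make_dose_record()] object, or `NULL` with `i_in` given.
#' @param gamma Material ratio delta/beta used for the propagation step.
#' @param distance_tag `"0"` (contact) or `"R"` (propagated).
#' @param m_a Number of equispaced view angles in `[0, pi)` (default
#'   `dose$m_a`).
#' @param seed RNG seed; `NULL` disables noise (noiseless scan).
#' @param i_in Per-angle incident fluence in photons/um^2 (default from
#'   `dose`).
#' @return Object of class `pbct_projset`: list with `fluence`
#'   (`[nx, ny, m_a]`), `flat` (`[nx, ny]`), `i_in`, `angles`,
#'   `distance_tag`, `pixel` (object-plane um), `tie_warning` (logical),
#'   `seed`.
#' @export
simulate_scan <- function(phantom, beam, detector, dose, gamma,
                          distance_tag = c("0", "R"),
                          m_a = if (!is.null(dose)) dose$m_a else 180L,
                          seed = 1,
                          i_in = if (!is.null(dose)) dose$i_in_2d else
                            stop_invalid("supply `dose` or `i_in`")) {
  distance_tag <- match.arg(distance_tag)
  pixel <- detector$pixel_pitch / beam$magnification
  if (abs(pixel - phantom$voxel) > 1e-6 * pixel)
    stop_invalid("phantom voxel (", phantom$voxel,
                 " um) must equal the object-plane pixel pitch/M (",
                 signif(pixel, 6), " um)")
  angles <- seq(0, pi, length.out = m_a + 1)[seq_len(m_a)]
  proj_beta <- xray_project(phantom$beta, angles, phantom$voxel)
  mu_int <- (4 * pi / beam$wavelength) * proj_beta
  n <- dim(proj_beta)
  p <- tie_param(gamma, beam)
  noisy <- !is.null(seed)
  tie_warning <- FALSE
  frames <- array(0, n)
  run <- function() {
    for (k in seq_len(n[3])) {
      i0 <- i_in * exp(-matrix(mu_int[, , k], n[1], n[2]))
      if (distance_tag == "R" && p$a > 0) {
        ir <- tie_forward_2d(i0, p, pixel)
        # TIE-Hom validity: a^2 |lap I| / I = |I_R - I_0| / I_0 <= 0.5
        if (max(abs(ir - i0) / i0) > 0.5) tie_warning <<- TRUE
        i0 <- ir
      }
      frames[, , k] <<- detect_frame(i0, detector, pixel,
                                     beam$magnification, noisy)
    }
    flat <- matrix(i_in, n[1], n[2])
    detect_frame(flat, detector, pixel, beam$magnification, noisy)
  }
  flat <- with_seed(seed, run())
  if (tie_warning)
    warning("TIE-Hom validity condition a^2|lap I|/I <= 0.5 violated in ",
            "at least one projection", call. = FALSE)
  structure(list(fluence = frames, flat = flat, i_in = i_in, angles = angles,
                 distance_tag = distance_tag, pixel = pixel,
                 tie_warning = tie_warning, seed = seed),
            class = "pbct_projset")
}
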