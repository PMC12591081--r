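# Dose accounting (air kerma, MGD) and the quality metrics Q_S, Q_C and
# measured gain factors.

# Bundled mass energy-absorption coefficients for dry air, m^2/kg.
.mu_en_rho_air <- c(`32` = 0.01366)

#' Air kerma per unit fluence
#'
#' `K_tr_air = (mu_en/rho)_air * E_ph`: the air kerma deposited per unit
#' photon fluence at the given energy, in Gy m^2. The mass energy-absorption
#' coefficient comes from a small bundled table (currently 32 keV) or can be
#' supplied directly.
#'
#' @param energy Photon energy in keV.
#' @param mu_en_rho Optional mass energy-absorption coefficient of air
#'   (m^2/kg) overriding the bundled table.
#' @return Kerma-per-fluence in Gy m^2.
#' @examples
#' k_tr_air(32)  # ~7.003e-17
#' @export
k_tr_air <- function(energy, mu_en_rho = NULL) {
  if (is.null(mu_en_rho)) {
    key <- as.character(energy)
    if (!key %in% names(.mu_en_rho_air))
      stop_invalid("no bundled (mu_en/rho)_air value at ", energy,
                   " keV; supply `mu_en_rho`")
    mu_en_rho <- .mu_en_rho_air[[key]]
  }
  e_ph <- energy * 1e3 * .const$e
  mu_en_rho * e_ph
}

#' Per-angle incident fluence from the entrance air kerma
#'
#' `I_in = K_air / (M_a * K_tr_air)`, the photon fluence per view angle
#' implied by an entrance-air-kerma budget split over `m_a` angles.
#'
#' @param k_air Entrance air kerma in Gy.
#' @param m_a Number of view angles.
#' @inheritParams k_tr_air
#' @return Fluence in photons per um^2.
#' @examples
#' fluence_from_kerma(8e-3, 600, 32)  # ~0.19
#' @export
fluence_from_kerma <- function(k_air, m_a, energy, mu_en_rho = NULL) {
  k_air / (m_a * k_tr_air(energy, mu_en_rho)) * .um^2
}

#' Intrinsic imaging quality Q_S
#'
#' `Q_S = SNR / (sqrt(I_in) * Deltabar^(n/2))`: the signal-to-noise ratio
#' normalised by the resolution volume and the incident fluence — the
#' information extracted per incident photon. For ideal Poisson detection
#' with voxel size equal to the resolution, `Q_S^2 = kappa * s^n` with
#' `s = voxel/resolution`, so `Q_S <= 1` for conventional imaging.
#'
#' @param snr Measured SNR.
#' @param deltabar Noise correlation width in micrometres.
#' @param fluence Incident fluence in photons/um^n per angle.
#' @param n Image dimensionality (default 2).
#' @return Dimensionless quality.
#' @examples
#' q_s(33.6, 83.2, 0.19)  # ~0.93
#' @export
q_s <- function(snr, deltabar, fluence, n = 2) {
  if (deltabar <= 0 || fluence <= 0) stop_invalid("inputs must be positive")
  snr / (sqrt(fluence) * deltabar^(n / 2))
}

#' Biomedical X-ray imaging quality Q_C (3D)
#'
#' `Q_C = C_m * SNR * sqrt(K_tr_air * L / (dose * Deltabar^3))`: per-photon
#' image quality weighted by the tissue contrast and normalised by the
#' (air-kerma-referred) radiation dose, for a reconstructed volume. `L` is
#' the mean path length through the sample, `V/Omega = (pi/2) * R_C` for a
#' cylinder.
#'
#' @param contrast_cm Modified contrast `C_m` between the two tissues.
#' @param snr Measured SNR of the reconstructed quantity.
#' @param k_tr_air Kerma-per-fluence in Gy m^2 (see [k_tr_air()]).
#' @param dose Mean glandular (or absorbed) dose in Gy.
#' @param depth_l Effective sample depth `L` in metres.
#' @param deltabar Resolution width in micrometres.
#' @return Dimensionless quality.
#' @export
q_c_3d <- function(contrast_cm, snr, k_tr_air, dose, depth_l, deltabar) {
  if (dose <= 0) stop_invalid("`dose` must be positive")
  if (deltabar <= 0 || depth_l <= 0) stop_invalid("inputs must be positive")
  contrast_cm * snr * sqrt(k_tr_air * depth_l / (dose * (deltabar * .um)^3))
}

#' Biomedical X-ray imaging quality Q_C (2D projection)
#'
#' Two-dimensional analogue of [q_c_3d()] with `Deltabar^2` and no depth
#' factor: `Q_C = C_m * SNR * sqrt(K_tr_air / (dose * Deltabar^2))`.
#'
#' @inheritParams q_c_3d
#' @return Dimensionless quality.
#' @export
q_c_2d <- function(contrast_cm, snr, k_tr_air, dose, deltabar) {
  if (dose <= 0) stop_invalid("`dose` must be positive")
  if (deltabar <= 0) stop_invalid("`deltabar` must be positive")
  contrast_cm * snr * sqrt(k_tr_air / (dose * (deltabar * .um)^2))
}

#' Image-level quality from total noise-equivalent quanta
#'
#' Image-level quality: the square root of the total number of
#' noise-equivalent quanta `NEQ_tot = M_vox * SNR^2` multiplied by the
#' squared contrast (and, for the dose-referred variant, the
#' energy-absorption ratio): `Q_img = sqrt(NEQ_tot * C^2 * ratio)`.
#'
#' @param snr Per-voxel SNR (uniform-map case), or `NULL` if `neq_total`
#'   is given directly.
#' @param n_vox Number of voxels/pixels in the image.
#' @param contrast Contrast of the feature of interest.
#' @param mass_absorption_ratio Optional energy-absorption weighting
#'   (default 1).
#' @param neq_total Total NEQ, overriding `snr`/`n_vox`.
#' @return Dimensionless image-level quality.
#' @export
q_image <- function(snr = NULL, n_vox = NULL, contrast = 1,
                    mass_absorption_ratio = 1, neq_total = NULL) {
  if (is.null(neq_total)) {
    if (is.null(snr) || is.null(n_vox))
      stop_invalid("supply `neq_total` or both `snr` and `n_vox`")
    neq_total <- n_vox * snr^2
  }
  sqrt(neq_total * contrast^2 * mass_absorption_ratio)
}

#' Theoretical SNR gain factors of phase retrieval
#'
#' Closed-form gains of TIE-Hom retrieval over contact imaging at matched
#' dose: `G1 = (4/pi)^(1/4) * (gamma/N_F)^(1/4)` (1D edge profiles) and
#' `G2 = (gamma/N_F)^(1/2)` (2D projections). Both are meaningful as gains
#' when `gamma/N_F > 1`.
#'
#' @param gamma Material ratio delta/beta.
#' @param n_f Fresnel number of the resolution element (see
#'   [fresnel_number()]).
#' @return Dimensionless gain.
#' @examples
#' gain_g2(869.4, 37.0)  # ~4.8
#' @export
gain_g2 <- function(gamma, n_f) {
  if (gamma <= 0 || n_f <= 0) stop_invalid("`gamma` and `n_f` must be positive")
  sqrt(gamma / n_f)
}

#' @rdname gain_g2
#' @export
gain_g1 <- function(gamma, n_f) {
  if (gamma <= 0 || n_f <= 0) stop_invalid("`gamma` and `n_f` must be positive")
  (4 / pi)^(1 / 4) * (gamma / n_f)^(1 / 4)
}

#' Measured gain factor from two quality reports
#'
#' Ratio of the intrinsic quality `Q_S` of a retrieved/propagated
#' measurement to a contact measurement at matched fluence and
#' reconstruction settings. When signal level and resolution match, the
#' ratio reduces to the plain SNR ratio.
#'
#' @param report_0 Quality report (or list with `snr`, optionally `q_s`,
#'   `scenario`) of the contact measurement.
#' @param report_r Same for the propagated + retrieved measurement.
#' @return Dimensionless gain.
#' @export
gain_from_measurements <- function(report_0, report_r) {
  s0 <- report_0$scenario %||% NA
  sr <- report_r$scenario %||% NA
  if (!identical(s0, sr))
    stop_invalid("reports come from different scenarios: ", s0, " vs ", sr)
  if (!is.null(report_0$q_s) && !is.null(report_r$q_s))
    return(report_r$q_s / report_0$q_s)
  report_r$snr / report_0$snr
}
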