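# Built-in study scenarios and bundled measurement tables.

#' Built-in imaging scenarios
#'
#' Returns the full configuration of one of the two bundled breast-CT study
#' scenarios, which share the beam (32 keV, R1 = 138 m, R2 = 5 m), material
#' (gamma = 869.4, adipose/glandular beta) and dose budget (8 mGy entrance
#' air kerma over 600 angles, MGD conversion c_D = 0.5) and differ in the
#' detector:
#'
#' * `"xineos"` — 99 um pitch, Gaussian PSF with Res = 150.7 um,
#'   energy-integrating, kappa = 0.865;
#' * `"eiger"` — 75 um pitch, rect PSF with Res = 86.2 um, photon counting,
#'   kappa = 1.
#'
#' @param name `"xineos"` or `"eiger"`.
#' @return Object of class `pbct_scenario`: a nested list with elements
#'   `scenario`, `beam`, `detector`, `material`, `dose` and `sample`.
#' @examples
#' sc <- pbct_scenario("eiger")
#' sc$detector$res
#' @export
pbct_scenario <- function(name = c("xineos", "eiger")) {
  name <- match.arg(name)
  det <- switch(name,
    xineos = list(pixel_pitch = 99, res = 150.7, psf_shape = "gaussian",
                  kappa = 0.865, mode = "energy_integrating"),
    eiger = list(pixel_pitch = 75, res = 86.2, psf_shape = "rect",
                 kappa = 1, mode = "photon_counting"))
  structure(list(
    scenario = name,
    beam = list(energy = 32, r1 = 138, r2 = 5),
    detector = det,
    material = list(gamma = 869.4, beta_adipose = 7.3e-11,
                    beta_glandular = 1.0e-10, beta_mean = 8.0e-11),
    dose = list(k_air = 8e-3, m_a = 600, c_d = 0.5, g = 0),
    sample = list(r_c = 0.055, height = 0.02)
  ), class = "pbct_scenario")
}

# Materialise the typed objects of a scenario config.
#' @noRd
scenario_objects <- function(sc) {
  beam <- make_beam(sc$beam$energy, sc$beam$r1, sc$beam$r2)
  detector <- make_detector(sc$detector$pixel_pitch, sc$detector$res,
                            sc$detector$psf_shape, sc$detector$kappa,
                            sc$detector$mode)
  dose <- make_dose_record(sc$dose$k_air, sc$dose$m_a, sc$beam$energy,
                           sc$dose$c_d, sc$dose$g)
  list(beam = beam, detector = detector, dose = dose)
}

#' Bundled flat-field and reconstruction SNR tables
#'
#' Returns one of the two bundled measurement tables of the reference
#' mastectomy study (six samples each, both detectors). Table 1 holds
#' flat-field projection SNRs `SNR[I0]` and the measured 2D retrieval gain;
#' Table 2 holds reconstructed-volume SNRs without (`snr_beta0`) and with
#' (`snr_beta_retr`) TIE-Hom retrieval, and the measured 3D gain. All values
#' are quoted at the published one-decimal precision.
#'
#' @param which 1 (projection SNRs) or 2 (reconstruction SNRs).
#' @return A data frame.
#' @examples
#' mean(pbct_table_snr(1)$eiger_snr0)  # ~33.6
#' @export
pbct_table_snr <- function(which = 1) {
  file <- system.file("extdata",
                      sprintf("table%d_snr.csv", as.integer(which)),
                      package = "pbct")
  if (file == "") stop_invalid("`which` must be 1 or 2")
  utils::read.csv(file)
}
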