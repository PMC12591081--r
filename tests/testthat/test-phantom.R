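# Phantom generator, dose record and scan simulator.

test_that("make_breast_phantom builds a consistent labelled cylinder", {
  ph <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 2, seed = 1)
  n <- dim(ph$beta)
  expect_identical(dim(ph$label), n)
  expect_true(all(ph$beta[ph$label == 0L] == 0))
  expect_true(all(ph$beta[ph$label == 1L] == ph$beta_adipose))
  expect_true(all(ph$beta[ph$label == 2L] == ph$beta_glandular))
  expect_gte(n[1] * 100e-6, 2 * 2e-3)  # grid spans the diameter
  # the two tissue means give C_m ~ 0.27
  expect_equal(contrast_cm(mean(ph$beta[ph$label == 1L]),
                           mean(ph$beta[ph$label == 2L])), 0.27)
})

test_that("phantom generation is deterministic and n_inclusions = 0 is uniform", {
  p1 <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 3, seed = 7)
  p2 <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 3, seed = 7)
  expect_identical(p1$beta, p2$beta)
  p3 <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 3, seed = 8)
  expect_false(identical(p3$beta, p1$beta))
  u <- make_breast_phantom(2e-3, 1e-3, 100, n_inclusions = 0)
  expect_identical(sort(unique(as.numeric(u$beta))), c(0, u$beta_adipose))
})

test_that("impossible inclusion placement fails after bounded retries", {
  expect_error(make_breast_phantom(2e-3, 1e-4, 100, n_inclusions = 60,
                                   seed = 1),
               "non-overlapping")
})

test_that("make_dose_record reproduces the study dose bookkeeping", {
  dr <- make_dose_record(8e-3, 600, 32, 0.5)
  expect_equal(dr$i_in_2d, 0.19, tolerance = 3e-3)
  expect_equal(dr$i_in_2d, dr$k_air / (dr$m_a * dr$k_tr_air) * 1e-12,
               tolerance = 5e-3)
  expect_equal(dr$mgd, 4e-3)
  expect_error(make_dose_record(0, 600, 32, 0.5), "k_air")
  expect_error(make_dose_record(8e-3, 600, 32, 0.5, g = 1), "g")
})

test_that("flat-field SNR follows Poisson statistics", {
  det <- make_detector(100, 1e-3, "gaussian", 1, "photon_counting")
  # mean count 1e4 per pixel at pitch 100 um -> i_in = 1 /um^2
  flat <- simulate_flat_field(1, c(320, 320), det, seed = 1)
  st <- measure_snr(flat)
  expect_equal(st$snr, 100, tolerance = 0.02)
  # kappa = 0.25 halves the SNR
  det_k <- make_detector(100, 1e-3, "gaussian", 0.25, "photon_counting")
  flat_k <- simulate_flat_field(1, c(320, 320), det_k, seed = 1)
  expect_equal(measure_snr(flat_k)$snr, 50, tolerance = 0.03)
})

test_that("photon-counting flat fields have variance/mean = 1 within 1%", {
  det <- make_detector(75, 86.2, "rect", 1, "photon_counting")
  i_in <- 0.19
  flat <- simulate_flat_field(i_in, c(320, 320), det, seed = 2,
                              magnification = 143 / 138)
  area <- (75 / (143 / 138))^2
  counts <- flat * area
  expect_equal(stats::var(as.numeric(counts)) / mean(counts), 1,
               tolerance = 0.01)
})

test_that("simulate_scan validates sampling and is deterministic", {
  b <- make_beam(32, 138, 5)
  det <- make_detector(99, 150.7, "gaussian", 0.865, "energy_integrating")
  ph <- make_breast_phantom(1.5e-3, 4 * 95.56e-6, 100, n_inclusions = 0)
  expect_error(simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 8,
                             i_in = 0.19),
               "pixel pitch")
  px <- det$pixel_pitch / b$magnification
  ph <- make_breast_phantom(1.5e-3, 4 * px * 1e-6, px, n_inclusions = 0)
  s1 <- simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 8, seed = 3,
                      i_in = 0.19)
  s2 <- simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 8, seed = 3,
                      i_in = 0.19)
  expect_identical(s1$fluence, s2$fluence)
  expect_identical(s1$flat, s2$flat)
  expect_length(s1$angles, 8)
  expect_true(all(diff(s1$angles) > 0))
})

test_that("photon flux is conserved between contact and propagated scans", {
  b <- make_beam(32, 138, 5)
  det <- make_detector(99, 150.7, "gaussian", 0.865, "energy_integrating")
  px <- det$pixel_pitch / b$magnification
  ph <- make_breast_phantom(1.5e-3, 4 * px * 1e-6, px, n_inclusions = 0)
  s0 <- simulate_scan(ph, b, det, NULL, 869.4, "0", m_a = 4, seed = NULL,
                      i_in = 0.19)
  sR <- simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 4, seed = NULL,
                      i_in = 0.19)
  expect_equal(mean(sR$fluence), mean(s0$fluence), tolerance = 1e-3)
})

test_that("an empty phantom scan is statistically identical to the flat field", {
  b <- make_beam(32, 138, 5)
  det <- make_detector(75, 86.2, "rect", 1, "photon_counting")
  px <- det$pixel_pitch / b$magnification
  ph <- list(beta = array(0, c(96, 16, 96)), voxel = px)
  class(ph) <- "pbct_phantom"
  scan <- simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 4, seed = 9,
                        i_in = 0.19)
  m_frames <- mean(scan$fluence)
  m_flat <- mean(scan$flat)
  # same expectation; both are Poisson means over >= 36k pixels
  expect_equal(m_frames, m_flat, tolerance = 0.01)
})
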