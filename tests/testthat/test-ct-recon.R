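# X-ray transform, FBP, and the PB-CT reconstruction pipelines.

make_cylinder <- function(n, ny, voxel, r_frac = 0.35, value = 1) {
  d <- voxel * 1e-6
  x <- (seq_len(n) - (n + 1) / 2) * d
  r2 <- outer(x^2, x^2, `+`)
  slice <- matrix(0, n, n)
  slice[r2 <= (r_frac * n * d)^2] <- value
  aperm(array(rep(slice, ny), c(n, n, ny)), c(1, 3, 2))
}

test_that("central ray of a uniform cylinder integrates to the chord length", {
  n <- 64; voxel <- 100
  vol <- make_cylinder(n, 1, voxel, r_frac = 0.3, value = 2)
  r_c <- 0.3 * n * voxel * 1e-6
  p <- xray_project(vol, c(0, pi / 3), voxel)
  ctr <- n / 2  # even grid: centre straddles samples; both are central rays
  expect_equal(p[ctr, 1, 1], 2 * 2 * r_c, tolerance = 0.02)
  # rotational symmetry of a centred cylinder
  expect_equal(p[, 1, 2], p[, 1, 1], tolerance = 0.01)
})

test_that("projection is linear and rejects empty angle lists", {
  set.seed(4)
  v1 <- array(runif(24^3), c(24, 24, 24))
  v2 <- array(runif(24^3), c(24, 24, 24))
  a <- c(0.3, 1.2)
  expect_equal(xray_project(v1 + 2 * v2, a, 50),
               xray_project(v1, a, 50) + 2 * xray_project(v2, a, 50))
  expect_error(xray_project(v1, numeric(0), 50), "angle")
})

test_that("backprojection is the exact adjoint of projection", {
  set.seed(5)
  nx <- 17; nz <- 13; ny <- 2
  angles <- runif(4, 0, pi)
  f <- array(rnorm(nx * ny * nz), c(nx, ny, nz))
  g <- array(rnorm(nx * ny * length(angles)), c(nx, ny, length(angles)))
  pf <- xray_project(f, angles, 80)
  ptg <- pbct:::xray_backproject(g, angles, 80, nx, nz)
  expect_equal(sum(pf * g), sum(f * ptg), tolerance = 1e-6)
})

test_that("fbp(xray_project(.)) recovers a smooth phantom to < 2% interior RMS", {
  n <- 96; ny <- 2; voxel <- 100
  d <- voxel * 1e-6
  x <- (seq_len(n) - (n + 1) / 2) * d
  r2 <- outer(x^2, x^2, `+`)
  slice <- exp(-r2 / (2 * (0.12 * n * d)^2))
  vol <- aperm(array(rep(slice, ny), c(n, n, ny)), c(1, 3, 2))
  m_a <- ceiling(pi / 2 * n / 2) + 5
  angles <- seq(0, pi, length.out = m_a + 1)[seq_len(m_a)]
  sino <- xray_project(vol, angles, voxel)
  rec <- fbp_reconstruct(sino, angles, voxel, apodize = FALSE)
  expect_false(attr(rec, "under_sampled"))
  ctr <- (n + 1) / 2
  ix <- seq(ceiling(ctr - 0.3 * n), floor(ctr + 0.3 * n))
  err <- rec[ix, , ix] - vol[ix, , ix]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(vol[ix, , ix]^2)), 0.02)
})

test_that("all-zero sinogram reconstructs to zero and under-sampling is flagged", {
  sino <- array(0, c(32, 1, 10))
  angles <- seq(0, pi, length.out = 11)[1:10]
  rec <- fbp_reconstruct(sino, angles, 100)
  expect_equal(max(abs(rec)), 0)
  expect_true(attr(rec, "under_sampled"))
  expect_error(fbp_reconstruct(sino, angles[1:5], 100), "does not match")
})

test_that("pbct_reconstruct requires a flat field and records provenance", {
  expect_error(pbct_reconstruct(list(fluence = array(1, c(8, 1, 4))),
                                tie_param(0, make_beam(32, 138, 5))),
               "flat")
})

test_that("conventional CT on contact projections recovers tissue beta within 2%", {
  b <- make_beam(32, 138, 5)
  det <- make_detector(99, 150.7, "gaussian", 0.865, "energy_integrating")
  px <- det$pixel_pitch / b$magnification
  n <- 64
  ph <- make_breast_phantom(0.3 * n * px * 1e-6, 6 * px * 1e-6, px,
                            n_inclusions = 0, seed = 1, margin = 1 / 0.3 / 2 - 1)
  ph$beta <- ph$beta[seq_len(n), , seq_len(n), drop = FALSE]
  ph$label <- ph$label[seq_len(n), , seq_len(n), drop = FALSE]
  scan <- simulate_scan(ph, b, det, NULL, 0, "0", m_a = 120, seed = NULL,
                        i_in = 0.19)
  rec <- pbct_reconstruct(scan, tie_param(0, b))
  inner <- ph$label == 1L & pbct:::gauss_smooth_fft(ph$label + 0, 2) > 0.999
  expect_equal(mean(rec$beta_hat[inner]), ph$beta_adipose, tolerance = 0.02)
  expect_identical(rec$provenance$retrieval_order, "none")
})

test_that("order A and order B agree to < 1% RMS on a weak smooth phantom", {
  b <- make_beam(32, 138, 5)
  p <- tie_param(869.4, b)
  n <- 72; ny <- 8
  px <- 99 / b$magnification
  d <- px * 1e-6
  x <- (seq_len(n) - (n + 1) / 2) * d
  r2 <- outer(x^2, x^2, `+`)
  blob <- 8e-11 * exp(-r2 / (2 * (0.18 * n * d)^2))
  ph <- list(beta = aperm(array(rep(blob, ny), c(n, n, ny)), c(1, 3, 2)),
             voxel = px)
  class(ph) <- "pbct_phantom"
  det <- make_detector(99, 150.7, "gaussian", 0.865, "energy_integrating")
  scan <- simulate_scan(ph, b, det, NULL, 869.4, "R", m_a = 120, seed = NULL,
                        i_in = 0.19)
  ra <- pbct_reconstruct(scan, p, "retrieve2d_then_fbp")
  rb <- pbct_reconstruct(scan, p, "fbp_then_retrieve3d")
  expect_lt(sqrt(mean((ra$beta_hat - rb$beta_hat)^2)) /
              sqrt(mean(ra$beta_hat^2)), 0.01)
  expect_identical(ra$provenance$retrieval_order, "retrieve2d_then_fbp")
  expect_identical(rb$provenance$retrieval_order, "fbp_then_retrieve3d")
})
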