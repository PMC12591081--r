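# TIE-Hom operators, real-space kernels, Fresnel oracle, edge contrast.

ref_beam <- make_beam(32, 138, 5)

# Circular "same" convolution of a periodic image/volume with a centred kernel.
circ_conv <- function(x, ker) {
  n <- dim(x)
  kd <- dim(ker)
  kb <- array(0, n)
  if (length(n) == 2) {
    kb[seq_len(kd[1]), seq_len(kd[2])] <- ker
    ctr <- (kd + 1) %/% 2
    kb <- kb[c(ctr[1]:n[1], seq_len(ctr[1] - 1)), c(ctr[2]:n[2], seq_len(ctr[2] - 1))]
  } else {
    kb[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- ker
    ctr <- (kd + 1) %/% 2
    kb <- kb[c(ctr[1]:n[1], seq_len(ctr[1] - 1)),
             c(ctr[2]:n[2], seq_len(ctr[2] - 1)),
             c(ctr[3]:n[3], seq_len(ctr[3] - 1))]
  }
  Re(stats::fft(stats::fft(x) * stats::fft(kb), inverse = TRUE)) / length(x)
}

test_that("tie_param matches the closed form and its trivial limits", {
  p <- tie_param(869.4, ref_beam)
  expect_equal(p$a, sqrt(869.4 * ref_beam$effective_distance *
                           ref_beam$wavelength / (4 * pi)))
  expect_equal(p$a * 1e6, 113.8, tolerance = 1e-3)  # hand arithmetic
  expect_equal(tie_param(0, ref_beam)$a, 0)
  # quadrupling R' doubles a
  b4 <- list(effective_distance = 4 * ref_beam$effective_distance,
             wavelength = ref_beam$wavelength)
  expect_equal(tie_param(869.4, b4)$a, 2 * p$a)
  expect_error(tie_param(-1, ref_beam), "gamma")
})

test_that("tie_forward_2d leaves a uniform image unchanged", {
  p <- tie_param(869.4, ref_beam)
  img <- matrix(3.7, 64, 64)
  expect_equal(tie_forward_2d(img, p, pixel = 100), img)
})

test_that("a pure sinusoid is an eigenfunction with gain 1 + 4 pi^2 a^2 rho^2", {
  p <- tie_param(869.4, ref_beam)
  n <- 64; pixel <- 100; d <- pixel * 1e-6
  kcyc <- 5  # cycles across the field
  rho <- kcyc / (n * d)
  s <- sin(2 * pi * kcyc * (seq_len(n) - 1) / n)
  img <- 10 + outer(s, rep(1, n))
  out <- tie_forward_2d(img, p, pixel, pad = FALSE)
  gain <- 1 + 4 * pi^2 * p$a^2 * rho^2
  expect_equal(out - 10, (img - 10) * gain, tolerance = 1e-10)
})

test_that("inverse(forward) is an exact round trip on periodic images", {
  p <- tie_param(869.4, ref_beam)
  set.seed(1)
  img <- matrix(rexp(64 * 64) + 1, 64, 64)
  back <- tie_inverse_2d(tie_forward_2d(img, p, 100, pad = FALSE), p, 100,
                         pad = FALSE)
  expect_lt(sqrt(mean((back - img)^2)) / sqrt(mean(img^2)), 1e-10)
})

test_that("all TIE-Hom operators preserve the mean and a = 0 is the identity", {
  p <- tie_param(869.4, ref_beam)
  p0 <- tie_param(0, ref_beam)
  set.seed(2)
  img <- matrix(runif(48 * 48) + 1, 48, 48)
  vol <- array(runif(24^3) + 1, c(24, 24, 24))
  expect_equal(mean(tie_forward_2d(img, p, 100, pad = FALSE)), mean(img))
  expect_equal(mean(tie_inverse_2d(img, p, 100, pad = FALSE)), mean(img))
  expect_equal(mean(tie_inverse_3d(vol, p, 100, pad = FALSE)), mean(vol))
  expect_identical(tie_forward_2d(img, p0, 100), img)
  expect_identical(tie_inverse_2d(img, p0, 100), img)
  expect_identical(tie_inverse_3d(vol, p0, 100), vol)
})

test_that("an ill-conditioned filter (a comparable to the field) errors", {
  p <- tie_param(869.4, ref_beam)  # a ~ 113.7 um
  expect_error(tie_inverse_2d(matrix(1, 16, 16), p, pixel = 10),
               "ill-conditioned")
})

test_that("kernel_k0 sums to one, decays monotonically and matches the Fourier inverse", {
  p <- tie_param(869.4, ref_beam)
  ker <- kernel_k0(p, pixel = 50)
  expect_equal(sum(ker), 1)
  expect_lt(abs(attr(ker, "raw_integral") - 1), 1e-3)
  m <- (nrow(ker) + 1) %/% 2
  profile <- ker[m, m:ncol(ker)]
  expect_true(all(diff(profile) <= 0))
  set.seed(2)
  img <- pbct:::gauss_smooth_fft(matrix(rnorm(256^2), 256, 256), 3) + 5
  y1 <- circ_conv(img, ker)
  y2 <- tie_inverse_2d(img, p, 50, pad = FALSE)
  expect_lt(sqrt(mean((y1 - y2)^2)) / stats::sd(y2), 0.005)
  expect_identical(dim(kernel_k0(tie_param(0, ref_beam), 50)), c(1L, 1L))
})

test_that("kernel_yukawa sums to one, matches the Fourier inverse, scales with a", {
  p <- tie_param(869.4, ref_beam)
  ker <- kernel_yukawa(p, voxel = 50)
  expect_equal(sum(ker), 1)
  expect_lt(abs(attr(ker, "raw_integral") - 1), 1e-3)
  set.seed(2)
  vol <- pbct:::gauss_smooth_fft(array(rnorm(64^3), c(64, 64, 64)), 3) + 5
  y1 <- circ_conv(vol, ker)
  y2 <- tie_inverse_3d(vol, p, 50, pad = FALSE)
  expect_lt(sqrt(mean((y1 - y2)^2)) / stats::sd(y2), 0.005)
  # halving a halves the kernel's deltabar width (sample on a matched grid)
  p_half <- list(a = p$a / 2, gamma = p$gamma)
  k1 <- kernel_yukawa(p, voxel = 25)
  k2 <- kernel_yukawa(p_half, voxel = 12.5)
  w1 <- psf_width_deltabar(k1, pixel = 25)
  w2 <- psf_width_deltabar(k2, pixel = 12.5)
  expect_equal(w1 / w2, 2, tolerance = 1e-3)
})

test_that("fresnel_propagate is unitary with trivial limits and aliasing guard", {
  n <- 128; pixel <- 10
  set.seed(3)
  base <- pbct:::gauss_smooth_fft(matrix(rnorm(n^2), n, n), 4)
  field <- sqrt(exp(base - max(base)))  # smooth positive amplitude
  expect_identical(fresnel_propagate(field, 0, 3.9e-11, pixel), field + 0i)
  pw <- matrix(1 + 0i, n, n)
  out <- fresnel_propagate(pw, 1, 3.9e-11, pixel)
  expect_equal(Mod(out), Mod(pw), tolerance = 1e-12)
  prop <- fresnel_propagate(field, 2, 3.9e-11, pixel)
  expect_equal(sum(Mod(prop)^2), sum(Mod(field)^2), tolerance = 1e-6)
  noisy <- matrix(rnorm(n^2), n, n)  # white field -> aliasing error
  expect_error(fresnel_propagate(noisy, 2, 3.9e-11, pixel), "sampling")
})

test_that("TIE-Hom forward agrees with the Fresnel oracle on a smooth blob", {
  # weakly absorbing monomorphous Gaussian blob, N_F >> 1
  b <- ref_beam
  p <- tie_param(869.4, b)
  n <- 256; pixel <- 40; d <- pixel * 1e-6
  x <- (seq_len(n) - (n + 1) / 2) * d
  r2 <- outer(x^2, x^2, `+`)
  # weak attenuation so the monomorphous phase (gamma/2 * ln I) stays
  # adequately sampled for the Fresnel oracle
  mu_int <- 0.02 * exp(-r2 / (2 * (12 * d)^2))
  i_in <- 1
  i0 <- i_in * exp(-mu_int)
  tie <- tie_forward_2d(i0, p, pixel, pad = FALSE)
  fld <- monomorphous_field(i0, i_in, 869.4)
  fr <- Mod(fresnel_propagate(fld, b$effective_distance, b$wavelength, pixel,
                              check_sampling = TRUE))^2
  expect_lt(sqrt(mean((tie - fr)^2)) / sqrt(mean((i0 - mean(i0))^2)), 0.01)
})

test_that("monomorphous_field ties phase to log-attenuation", {
  i0 <- matrix(c(0.5, 0.8, 1, 0.9), 2, 2)
  f <- monomorphous_field(i0, 1, 100)
  expect_equal(Mod(f)^2, i0)
  expect_equal(f, sqrt(i0) * exp(1i * (100 / 2) * log(i0)))
  expect_error(monomorphous_field(matrix(0, 2, 2), 1, 100), "positive")
})

test_that("edge_contrast trivial limits and validity errors", {
  lam <- ref_beam$wavelength
  expect_equal(edge_contrast(0, lam, 4.83, 100, 1e-3), 0)
  expect_equal(edge_contrast(1e-7, lam, 0, 100, 1e-3), 0)
  expect_equal(edge_contrast(1e-7, lam, 4.83, 100, 0), 0)
  expect_error(edge_contrast(1e-7, lam, 4.83, 1, 1e-3), "N_F")
  expect_error(edge_contrast(1e-6, lam, 4.83, 50, 2e-3), "contrast")
})

test_that("edge_contrast agrees with the Fresnel oracle over a sweep", {
  # blurred phase step, weak absorption; fringe contrast of the propagated
  # fluence vs the closed form, within 10% for N_F >= 5
  b <- ref_beam
  lam <- b$wavelength
  n <- 2048
  delta <- 4e-8
  thick <- 1e-4
  for (n_f in c(5, 10, 20)) {
    res_m <- sqrt(n_f * b$effective_distance * lam)
    pixel <- res_m * 1e6 / 16
    d <- pixel * 1e-6
    x <- (seq_len(n) - n / 2) * d
    t_proj <- thick * stats::pnorm(x / (res_m / (2 * sqrt(pi))))
    phi <- -2 * pi * delta * t_proj / lam
    amp <- outer(exp(1i * phi), rep(1, 8))
    out <- Mod(fresnel_propagate(amp, b$effective_distance, lam, pixel,
                                 check_sampling = FALSE))^2
    prof <- rowMeans(out)
    core <- prof[seq(n / 4, 3 * n / 4)]
    meas <- (max(core) - min(core)) / (max(core) + min(core))
    pred <- edge_contrast(delta, lam, b$effective_distance, res_m * 1e6, thick)
    expect_equal(meas, pred, tolerance = 0.1)
  }
})

test_that("retrieval commutes with projection on a smooth phantom (small grid)", {
  b <- ref_beam
  p <- tie_param(869.4, b)
  n <- 64; voxel <- 95.6
  d <- voxel * 1e-6
  x <- (seq_len(n) - (n + 1) / 2) * d
  r2 <- array(0, c(n, n, n))
  r2 <- r2 + x^2 + rep(x^2, each = n) + rep(x^2, each = n * n)
  vol <- exp(-r2 / (2 * (8 * d)^2))
  angles <- c(0, pi / 5, pi / 2)
  proj_then_ret <- xray_project(vol, angles, voxel)
  for (k in seq_along(angles))
    proj_then_ret[, , k] <- tie_inverse_2d(proj_then_ret[, , k], p, voxel)
  ret_then_proj <- xray_project(tie_inverse_3d(vol, p, voxel), angles, voxel)
  expect_lt(sqrt(mean((proj_then_ret - ret_then_proj)^2)) /
              sqrt(mean(ret_then_proj^2)), 0.01)
})
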