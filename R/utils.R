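# Internal helpers: constants, unit conversion, FFT grids, padding, RNG scoping.

# Physical constants. h and c are kept at the 4-digit values used throughout
# the worked scenario numbers so that derived quantities (photon energy,
# wavelength) match those numbers to the quoted precision.
.const <- list(
  h = 6.626e-34,           # Planck constant, J s
  c = 2.998e8,             # speed of light, m/s
  e = 1.602176634e-19      # elementary charge, J/eV (exact)
)

.um <- 1e-6  # metres per micrometre

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# DFT sample frequencies (cycles per unit length), e^(-2*pi*i) convention,
# in standard FFT wrap-around order. Equivalent to numpy.fft.fftfreq.
#' @noRd
fft_freq <- function(n, d = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Squared radial frequency grid for a 2D field (cycles^2 per unit^2).
#' @noRd
freq_rho2_2d <- function(dims, d) {
  fx <- fft_freq(dims[1], d)
  fy <- fft_freq(dims[2], d)
  outer(fx^2, fy^2, `+`)
}

# Squared radial frequency grid for a 3D field.
#' @noRd
freq_rho2_3d <- function(dims, d) {
  fx <- fft_freq(dims[1], d)
  fy <- fft_freq(dims[2], d)
  fz <- fft_freq(dims[3], d)
  r2 <- array(0, dims)
  r2 <- r2 + fx^2                                  # recycles down dim 1
  r2 <- r2 + rep(fy^2, each = dims[1])             # dim 2
  r2 <- r2 + rep(fz^2, each = dims[1] * dims[2])   # dim 3
  r2
}

# Mirror (symmetric) padding of a matrix by `p` samples on every side.
#' @noRd
pad_mirror_2d <- function(img, p) {
  if (p <= 0) return(img)
  n <- dim(img)
  p1 <- min(p, n[1]); p2 <- min(p, n[2])
  ix <- c(rev(seq_len(p1)), seq_len(n[1]), n[1] - seq_len(p1) + 1L)
  iy <- c(rev(seq_len(p2)), seq_len(n[2]), n[2] - seq_len(p2) + 1L)
  img[ix, iy, drop = FALSE]
}

#' @noRd
crop_2d <- function(img, p, n) {
  p1 <- min(p, (dim(img)[1] - n[1]) %/% 2)
  p2 <- min(p, (dim(img)[2] - n[2]) %/% 2)
  img[p1 + seq_len(n[1]), p2 + seq_len(n[2]), drop = FALSE]
}

#' @noRd
pad_mirror_3d <- function(vol, p) {
  if (p <= 0) return(vol)
  n <- dim(vol)
  idx <- lapply(n, function(ni) {
    pi <- min(p, ni)
    c(rev(seq_len(pi)), seq_len(ni), ni - seq_len(pi) + 1L)
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' @noRd
crop_3d <- function(vol, p, n) {
  off <- pmin(p, (dim(vol) - n) %/% 2)
  vol[off[1] + seq_len(n[1]), off[2] + seq_len(n[2]), off[3] + seq_len(n[3]),
      drop = FALSE]
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Gaussian low-pass of a 2D/3D array via FFT (periodic), sigma in samples.
#' @noRd
gauss_smooth_fft <- function(x, sigma) {
  if (sigma <= 0) return(x)
  dims <- dim(x)
  r2 <- if (length(dims) == 2) freq_rho2_2d(dims, 1) else freq_rho2_3d(dims, 1)
  h <- exp(-2 * pi^2 * sigma^2 * r2)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / length(x)
}
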