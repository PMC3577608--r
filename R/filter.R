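# Chebyshev Type I band-pass design and zero-phase filtering.
#
# The temporal filter is designed in zero-pole-gain form (analog Chebyshev I
# low-pass prototype -> low-pass-to-band-pass transform -> bilinear transform)
# and realized as a cascade of second-order sections (biquads), which stays
# numerically stable at the very low normalized cut-offs typical of
# resting-state BOLD (0.01 Hz at a 2 s sampling interval). Filtering is applied
# forward and backward with steady-state initial conditions and odd-symmetric
# edge padding, so the net filter has zero phase.

#' Design a Chebyshev Type I band-pass filter as second-order sections
#'
#' @param low_hz,high_hz pass-band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param fs sampling frequency in Hz.
#' @param order prototype low-pass order; the band-pass filter has `2 * order`
#'   poles. Default 4.
#' @param ripple_db pass-band ripple in dB. Default 0.5.
#' @return A list with `sos` (an `order` x 6 matrix, columns
#'   `b0 b1 b2 a0 a1 a2` with `a0 = 1`) suitable for [sosfiltfilt()].
#' @examples
#' f <- cheby1_bandpass(0.01, 0.08, fs = 0.5)
#' dim(f$sos)
#' @export
cheby1_bandpass <- function(low_hz, high_hz, fs, order = 4L, ripple_db = 0.5) {
  stopifnot(is.numeric(low_hz), is.numeric(high_hz), is.numeric(fs))
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < Nyquist (", nyq,
         " Hz); got [", low_hz, ", ", high_hz, "]")
  }
  if (order < 1) stop("order must be >= 1")

  # analog low-pass prototype (cut-off 1 rad/s)
  eps <- sqrt(10^(ripple_db / 10) - 1)
  mu <- asinh(1 / eps) / order
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  gain <- Re(prod(-p))
  if (order %% 2 == 0) gain <- gain / sqrt(1 + eps^2)

  # pre-warped band edges (normalized to Nyquist, bilinear fs = 2)
  fs2 <- 4
  w1 <- fs2 * tan(pi * (low_hz / nyq) / 2)
  w2 <- fs2 * tan(pi * (high_hz / nyq) / 2)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # low-pass -> band-pass in zpk form: n poles -> 2n poles, n zeros at s = 0
  ps <- p * bw / 2
  disc <- sqrt(ps^2 - w0^2)
  p_bp <- c(ps + disc, ps - disc)
  z_bp <- rep(0 + 0i, order)
  k_bp <- gain * bw^order

  # bilinear transform (fs2 = 4): s -> z
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)              # n zeros at z = +1
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))  # n zeros at z = -1
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))

  # pair conjugate poles into biquads; each section gets one zero at +1 and one
  # at -1 (numerator z^2 - 1), so every section is itself a band-pass
  idx <- order(-Mod(p_d))          # poles nearest the unit circle first
  p_sorted <- p_d[idx]
  pos <- p_sorted[Im(p_sorted) > 0]
  if (length(pos) != order) {
    # real poles possible for odd orders / wide bands: pair by conjugates anyway
    pos <- p_sorted[seq(1, length(p_sorted), by = 2)]
  }
  sos <- matrix(0, nrow = order, ncol = 6)
  for (s in seq_len(order)) {
    pk <- pos[s]
    a <- c(1, -2 * Re(pk), Mod(pk)^2)
    b <- c(1, 0, -1)
    sos[s, ] <- c(b, a)
  }
  # overall gain on the first section
  sos[1, 1:3] <- sos[1, 1:3] * k_d
  list(sos = sos, low_hz = low_hz, high_hz = high_hz, fs = fs,
       order = order, ripple_db = ripple_db)
}

# steady-state (unit-step) initial conditions per section, cumulative DC gains
sos_step_zi <- function(sos) {
  n_sec <- nrow(sos)
  zi <- matrix(0, nrow = n_sec, ncol = 2)
  scale <- 1
  for (s in seq_len(n_sec)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h1 <- sum(b) / sum(a)
    z2 <- b[3] - a[3] * h1
    z1 <- b[2] - a[2] * h1 + z2
    zi[s, ] <- scale * c(z1, z2)
    scale <- scale * h1
  }
  zi
}

#' Zero-phase filtering with second-order sections
#'
#' Applies the cascade forward and backward (so the effective magnitude
#' response is squared and the phase response is zero), with odd-symmetric
#' padding of `3 * (2 * nrow(sos) + 1)` samples at each end and steady-state
#' initial conditions, mirroring the behaviour of standard forward-backward
#' filtering routines.
#'
#' @param filt a filter from [cheby1_bandpass()] (or any list with an `sos`
#'   matrix).
#' @param x numeric vector to filter.
#' @return filtered vector, same length as `x`.
#' @export
sosfiltfilt <- function(filt, x) {
  sos <- filt$sos
  stopifnot(is.matrix(sos), ncol(sos) == 6, is.numeric(x))
  padlen <- 3L * (2L * nrow(sos) + 1L)
  n <- length(x)
  if (n <= padlen) {
    stop("series too short for zero-phase filtering: need > ", padlen,
         " samples, got ", n)
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- sos_step_zi(sos)
  y <- sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}
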