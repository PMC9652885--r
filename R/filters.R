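# Butterworth band-pass design (zpk -> bilinear -> second-order sections)
# and zero-phase forward-backward filtering.  Implemented in-package because
# the target environment carries no DSP library; the contract is the
# magnitude/phase behaviour, checked against analytic oracles in the tests.

#' Design a digital Butterworth band-pass filter as second-order sections
#'
#' Analog Butterworth prototype, low-pass-to-band-pass transform with
#' pre-warped edges, bilinear transform, and factorization into biquads.
#' Each section carries one zero at z = 1 and one at z = -1; the cascade
#' gain is normalized to exactly 1 at the (warped) band center.
#'
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Design order `n` of the analog prototype (the band-pass has
#'   `2n` poles; applied forward-backward the effective magnitude order is
#'   `2 x` the design order).
#' @return A `butter_sos` object: list with `sos` (n_sections x 6 matrix of
#'   `b0 b1 b2 a0 a1 a2`), and the design parameters.
#' @export
butter_bandpass <- function(low, high, fs, order = 6) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs too low for band?)")
  n <- as.integer(order)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
  # bilinear transform; n analog zeros at s = 0 map to z = 1, the remaining
  # n zeros of the 2n-pole digital filter sit at z = -1
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  # group poles into conjugate (or real) pairs, poles nearest the unit
  # circle placed in the last sections
  cplx <- p_d[Im(p_d) > 1e-10]
  realp <- Re(p_d[abs(Im(p_d)) <= 1e-10])
  sections <- vector("list", n)
  s <- 0L
  for (p in cplx[order(Mod(cplx))]) {
    s <- s + 1L
    sections[[s]] <- c(1, -2 * Re(p), Mod(p)^2)
  }
  if (length(realp) > 0) {
    realp <- sort(realp)
    for (i in seq(1, length(realp), by = 2)) {
      s <- s + 1L
      sections[[s]] <- c(1, -(realp[i] + realp[i + 1]), realp[i] * realp[i + 1])
    }
  }
  stopifnot(s == n)
  sos <- t(vapply(sections, function(a) c(1, 0, -1, a), numeric(6)))
  # normalize cascade gain to 1 at the warped band center
  fc <- atan(w0 / fs2) / pi * fs
  z <- exp(2i * pi * fc / fs)
  h <- prod(apply(sos, 1, function(r)
    (r[1] + r[2] / z + r[3] / z^2) / (r[4] + r[5] / z + r[6] / z^2)))
  sos[1, 1:3] <- sos[1, 1:3] / Mod(h)
  structure(list(sos = sos, low = low, high = high, fs = fs, order = n),
            class = "butter_sos")
}

#' Frequency response of a biquad cascade
#'
#' @param filt A `butter_sos`.
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Complex response values.
#' @export
sos_freq_response <- function(filt, f) {
  z <- exp(2i * pi * f / filt$fs)
  vapply(z, function(zz)
    prod(apply(filt$sos, 1, function(r)
      (r[1] + r[2] / zz + r[3] / zz^2) / (r[4] + r[5] / zz + r[6] / zz^2))),
    complex(1))
}

# steady-state initial conditions per section for a unit-amplitude step,
# scaled by the cumulative DC gain of the preceding sections
sos_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h <- sum(b) / sum(a)
    zi[s, 1] <- scale * (b[2] + b[3] - (a[2] + a[3]) * h)
    zi[s, 2] <- scale * (b[3] - a[3] * h)
    scale <- scale * h
  }
  zi
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the cascade forward and backward with odd-symmetric edge
#' extension and steady-state initial conditions, so in-band components
#' come through with zero net phase shift.
#'
#' @param filt A `butter_sos`.
#' @param x Numeric vector.
#' @param padlen Edge-extension length in samples; default
#'   `3 * fs / low` (three periods of the low band edge), capped at
#'   `length(x) - 1`.
#' @return Filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(filt, x, padlen = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short to filter")
  padlen <- min(n - 1L, as.integer(padlen %||% ceiling(3 * filt$fs / filt$low)))
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- sos_zi(filt$sos)
  y <- .sosfilt_cpp(filt$sos, ext, zi * ext[1])
  y <- rev(y)
  y <- .sosfilt_cpp(filt$sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}
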