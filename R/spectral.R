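#' The nine-band sub-division of the 1-50 Hz EEG spectrum
#'
#' delta 1-4, theta 4-8, low alpha 8-10, high alpha 10-12, alpha 8-12,
#' low beta 12-18, high beta 18-30, beta 12-30, gamma 30-50 Hz.  Band edges
#' are half-open `[low, high)` so the five primary bands (delta, theta,
#' alpha, beta, gamma) partition the 1-50 Hz total band exactly.
#'
#' @return A `band_scheme`: list with `bands` (named list of length-2
#'   ranges), `total` (c(1, 50)), `primary` (the five partitioning bands),
#'   `pac_low` / `pac_high` (band names used as phase and amplitude bands
#'   in phase-amplitude coupling).
#' @export
band_scheme <- function() {
  bands <- list(delta = c(1, 4), theta = c(4, 8),
                alphaL = c(8, 10), alphaH = c(10, 12), alpha = c(8, 12),
                betaL = c(12, 18), betaH = c(18, 30), beta = c(12, 30),
                gamma = c(30, 50))
  structure(list(bands = bands, total = c(1, 50),
                 primary = c("delta", "theta", "alpha", "beta", "gamma"),
                 pac_low = c("delta", "theta"),
                 pac_high = c("alphaL", "alphaH", "alpha",
                              "betaL", "betaH", "beta", "gamma")),
            class = "band_scheme")
}

#' Welch power spectral density estimate
#'
#' Hann-tapered segments of `seg_seconds` (default 1 s, i.e. 1 Hz
#' resolution) with 50% overlap, averaged; one-sided density scaling so
#' that `sum(psd) * df` equals the signal power.  `method = "periodogram"`
#' uses a single rectangular-window periodogram instead (kept as the
#' independent oracle path for the band-power tests).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_seconds Welch segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @param method `"welch"` or `"periodogram"`.
#' @return List with `freq` (Hz), `psd` (uV^2/Hz) and `df` (Hz bin width).
#' @export
welch_psd <- function(x, fs, seg_seconds = 1, overlap = 0.5,
                      method = c("welch", "periodogram")) {
  method <- match.arg(method)
  n <- length(x)
  x <- x - mean(x)
  if (method == "periodogram") {
    X <- fft(x)
    nf <- n %/% 2 + 1
    psd <- (Mod(X[seq_len(nf)])^2) / (fs * n)
    # one-sided: double everything except DC and (for even n) Nyquist
    dbl <- 2:(if (n %% 2 == 0) nf - 1 else nf)
    psd[dbl] <- 2 * psd[dbl]
    return(list(freq = (seq_len(nf) - 1) * fs / n, psd = psd, df = fs / n))
  }
  seg <- as.integer(round(fs * seg_seconds))
  if (seg > n) seg <- n
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- hann_window(seg)
  M <- vapply(starts, function(s) {
    xi <- x[s:(s + seg - 1L)]
    (xi - mean(xi)) * w
  }, numeric(seg))
  X <- mvfft(M)
  nf <- seg %/% 2 + 1
  P <- rowMeans(Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * sum(w^2))
  P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
  if (seg %% 2 != 0) P[nf] <- 2 * P[nf]
  list(freq = (seq_len(nf) - 1) * fs / seg, psd = P, df = fs / seg)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Absolute band power
#'
#' Integral of the power spectral estimate over the half-open band
#' `[low, high)`, in uV^2.  Scales as `a^2` under amplitude scaling.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 numeric `(low, high)` in Hz, inside `(0, fs/2)`.
#' @param method Spectral estimator, see [welch_psd()].
#' @return Nonnegative scalar.
#' @export
band_power <- function(x, fs, band, method = c("welch", "periodogram")) {
  if (!(band[1] > 0 && band[2] > band[1] && band[2] <= fs / 2))
    stop("band must lie inside (0, fs/2)")
  if (length(x) < 2 * fs / band[1])
    warning("signal shorter than ~2 cycles of the lower band edge")
  p <- welch_psd(x, fs, method = match.arg(method))
  sel <- p$freq >= band[1] & p$freq < band[2]
  sum(p$psd[sel]) * p$df
}

#' Absolute power in all nine sub-bands (plus the total band)
#'
#' One spectral estimate shared across bands, so sub-band additivity holds
#' exactly on the common frequency grid.
#'
#' @inheritParams band_power
#' @param scheme A [band_scheme()].
#' @return Named vector of the 9 band powers, with attribute `"total"`
#'   holding the 1-50 Hz total-band power.
#' @export
band_powers <- function(x, fs, scheme = band_scheme(),
                        method = c("welch", "periodogram")) {
  p <- welch_psd(x, fs, method = match.arg(method))
  pw <- vapply(scheme$bands, function(b)
    sum(p$psd[p$freq >= b[1] & p$freq < b[2]]) * p$df, numeric(1))
  tot <- sum(p$psd[p$freq >= scheme$total[1] & p$freq < scheme$total[2]]) *
    p$df
  attr(pw, "total") <- tot
  pw
}

#' Relative band power
#'
#' Each band's absolute power divided by the total-band (1-50 Hz) power.
#' Scale-invariant; the five primary bands sum to 1.
#'
#' @param powers Named band-power vector from [band_powers()].
#' @param total Total-band power; taken from the `"total"` attribute when
#'   missing.
#' @return Named vector of relative powers in `[0, 1]`.
#' @export
relative_band_power <- function(powers, total = attr(powers, "total")) {
  if (is.null(total)) stop("total-band power required")
  if (total <= 0) stop("degenerate signal: total-band power is zero")
  powers / total
}

#' Inter-hemispheric band-power asymmetry
#'
#' Differential asymmetry `DASM = left - right` and rational asymmetry
#' `RASM = left / right` of absolute band powers of a symmetric electrode
#' pair.
#'
#' @param left_power,right_power Nonnegative band powers (scalars or
#'   aligned vectors, e.g. one value per band).
#' @param rasm_on_zero `"error"` (default) or a numeric sentinel returned
#'   where `right_power == 0`.
#' @return List with `dasm` and `rasm`.
#' @export
asymmetry <- function(left_power, right_power, rasm_on_zero = "error") {
  stopifnot(all(left_power >= 0), all(right_power >= 0))
  dasm <- left_power - right_power
  zero <- right_power == 0
  if (any(zero) && identical(rasm_on_zero, "error"))
    stop("right-hemisphere power is zero; RASM undefined")
  rasm <- left_power / right_power
  if (any(zero)) rasm[zero] <- rasm_on_zero
  list(dasm = dasm, rasm = rasm)
}
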