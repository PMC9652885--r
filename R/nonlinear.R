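#' Parameters for the nonlinear feature family
#'
#' @param entropy_bins Number of equal-width amplitude bins for the Shannon
#'   entropy histogram.
#' @param lyap_embed_dim Embedding dimension K for the largest Lyapunov
#'   exponent.
#' @param lyap_delay Embedding delay in samples; `NULL` = first lag at
#'   which the autocorrelation drops to 1 - 1/e of its initial value (the
#'   canonical choice for nearest-neighbour divergence estimators; a
#'   zero-crossing rule over-embeds strongly mixing signals).
#' @param lyap_fit_range Number of divergence steps used for the slope fit;
#'   `NULL` = half a mean period (at least 4 steps).
#' @param lyap_max_ref Cap on the number of reference points for the
#'   divergence average (evenly strided subsample; all points remain
#'   neighbour candidates).  Bounds the quadratic neighbour search.
#' @param hurst_window_sizes Ladder of R/S window sizes; `NULL` = 8
#'   geometric sizes between 64 (16 for short signals) and n/2.
#' @param lz_binarize Binarization threshold for Lempel-Ziv complexity,
#'   `"median"` or `"mean"`.
#' @return A `nonlinear_params` list.
#' @export
nonlinear_params <- function(entropy_bins = 64, lyap_embed_dim = 5,
                             lyap_delay = NULL, lyap_fit_range = NULL,
                             lyap_max_ref = 400,
                             hurst_window_sizes = NULL,
                             lz_binarize = c("median", "mean")) {
  stopifnot(entropy_bins >= 2, lyap_embed_dim >= 2, lyap_max_ref >= 10)
  structure(list(entropy_bins = as.integer(entropy_bins),
                 lyap_embed_dim = as.integer(lyap_embed_dim),
                 lyap_delay = lyap_delay, lyap_fit_range = lyap_fit_range,
                 lyap_max_ref = as.integer(lyap_max_ref),
                 hurst_window_sizes = hurst_window_sizes,
                 lz_binarize = match.arg(lz_binarize)),
            class = "nonlinear_params")
}

#' Shannon entropy of the amplitude distribution
#'
#' Histogram of the samples into `bins` equal-width bins spanning
#' `[min(x), max(x)]`; entropy in nats, bounded by `log(bins)`.
#' A constant signal occupies a single bin and returns 0.
#'
#' @param x Numeric vector.
#' @param bins Number of bins.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(x, bins = 64) {
  stopifnot(bins >= 2, length(x) >= 2)
  r <- range(x)
  if (r[1] == r[2]) return(0)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Hjorth parameters
#'
#' Activity (population variance), mobility (ratio of the standard
#' deviation of the first difference to that of the signal), and
#' complexity (mobility of the first difference over mobility of the
#' signal).  For a pure sinusoid at frequency f, mobility is
#' `2 sin(pi f / fs)` and complexity is 1.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 3)
  varp <- function(v) mean((v - mean(v))^2)
  a <- varp(x)
  if (a == 0) stop("zero-variance signal: mobility/complexity undefined")
  d1 <- diff(x)
  d2 <- diff(d1)
  mob <- sqrt(varp(d1) / a)
  mob_d <- sqrt(varp(d2) / varp(d1))
  c(activity = a, mobility = mob, complexity = mob_d / mob)
}

#' Normalized Lempel-Ziv (LZ76) complexity
#'
#' Binarizes the signal at its median (or mean), counts the distinct
#' phrases `c(n)` of the Lempel-Ziv 1976 exhaustive parsing, and returns
#' `c(n) / b(n)` with `b(n) = n / log2(n)`.  Approaches 1 for i.i.d.
#' random bits; near 0 for constant sequences.
#'
#' @param x Numeric vector (length >= 16 recommended) or a logical/0-1
#'   vector taken as the binary sequence directly.
#' @param binarize `"median"` or `"mean"`.
#' @return Normalized complexity (dimensionless).
#' @export
lempel_ziv_complexity <- function(x, binarize = c("median", "mean")) {
  binarize <- match.arg(binarize)
  n <- length(x)
  stopifnot(n >= 2)
  bits <- if (is.logical(x) || all(x %in% c(0, 1))) as.integer(x)
  else {
    thr <- if (binarize == "median") median(x) else mean(x)
    as.integer(x > thr)
  }
  cn <- .lz76_cpp(bits)
  cn * log2(n) / n
}

#' Hurst exponent by rescaled-range (R/S) analysis
#'
#' For each window size in a geometric ladder, the rescaled range
#' `R/S` (range of the cumulative mean-deviation over the sample standard
#' deviation) is averaged over non-overlapping windows; H is the slope of
#' `log(R/S)` against `log(size)`.  Estimates outside `(0, 1)` trigger a
#' warning and are clipped to `(0, 1.2)`.
#'
#' @param x Numeric vector (length >= 256 recommended).
#' @param window_sizes Ladder of window sizes; default 8 geometric sizes
#'   from 64 (16 when `length(x) < 1024`, a small-sample bias guard) up to
#'   `length(x)/2`.
#' @return Estimated Hurst exponent.
#' @export
hurst_exponent <- function(x, window_sizes = NULL) {
  n <- length(x)
  stopifnot(n >= 32)
  if (is.null(window_sizes)) {
    wmin <- if (n >= 1024) 64 else 16
    window_sizes <- unique(round(exp(seq(log(wmin), log(n / 2),
                                         length.out = 8))))
  }
  window_sizes <- window_sizes[window_sizes >= 8 & window_sizes <= n %/% 2]
  rs <- rep(NA_real_, length(window_sizes))
  for (i in seq_along(window_sizes)) {
    s <- window_sizes[i]
    k <- n %/% s
    m <- matrix(x[seq_len(k * s)], nrow = s)
    mu <- colMeans(m)
    dev <- sweep(m, 2, mu)
    cs <- apply(dev, 2, cumsum)
    if (k == 1) cs <- matrix(cs, ncol = 1)
    R <- apply(cs, 2, max) - apply(cs, 2, min)
    S <- sqrt(colSums(dev^2) / (s - 1))
    ok <- S > 0
    if (any(ok)) rs[i] <- mean(R[ok] / S[ok])
  }
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) stop("degenerate signal: R/S undefined at all window sizes")
  lx <- log(window_sizes[ok]); ly <- log(rs[ok])
  h <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  if (h <= 0 || h >= 1) {
    warning("Hurst estimate ", signif(h, 3), " outside (0, 1); clipped")
    h <- min(max(h, 1e-6), 1.2)
  }
  h
}

# autocorrelation via FFT; returns lags 0..n-1 (biased estimator)
autocorr_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  nfft <- nextn(2 * n, 2)
  X <- fft(c(xc, rep(0, nfft - n)))
  ac <- Re(fft(Mod(X)^2, inverse = TRUE))[seq_len(n)]
  ac / ac[1]
}

#' Largest Lyapunov exponent (Rosenstein nearest-neighbour divergence)
#'
#' Delay-embeds the series in K dimensions, finds each point's nearest
#' neighbour outside a Theiler window of one mean period, tracks the mean
#' log distance of the neighbour pairs over time, and returns the slope of
#' the initial linear region divided by the sampling period.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz); the exponent is returned per second
#'   (use `fs = 1` for per-step units, e.g. maps).
#' @param params A [nonlinear_params()].
#' @return Estimated largest Lyapunov exponent (1/s).
#' @export
lyapunov_exponent <- function(x, fs, params = nonlinear_params()) {
  n <- length(x)
  if (var(x) == 0) stop("constant signal: no valid neighbour distances")
  zc <- sum(diff(sign(x - mean(x))) != 0)
  if (zc < 2) stop("signal has no oscillation about its mean")
  mean_period <- max(2, 2 * n / zc)
  tau <- params$lyap_delay
  if (is.null(tau)) {
    ac <- autocorr_fft(x)
    tau <- which(ac <= 1 - exp(-1))[1] - 1L
    if (is.na(tau) || tau < 1) tau <- 1L
    tau <- min(tau, max(1L, (n - 1L) %/% (2L * params$lyap_embed_dim)))
  }
  maxstep <- as.integer(params$lyap_fit_range %||%
                          max(4, round(0.5 * mean_period)))
  m <- params$lyap_embed_dim
  M <- n - (m - 1) * tau
  if (M <= maxstep + 2)
    stop("signal too short for embedding dimension ", m, " and delay ", tau)
  div <- .lyap_divergence_cpp(x, m, as.integer(tau),
                              as.integer(round(mean_period)),
                              as.integer(maxstep), params$lyap_max_ref)
  steps <- which(is.finite(div)) - 1L
  if (length(steps) < 3) stop("no valid neighbour divergences")
  d <- div[steps + 1L]
  slope <- sum((steps - mean(steps)) * (d - mean(d))) /
    sum((steps - mean(steps))^2)
  slope * fs
}

#' Phase-amplitude coupling by envelope coherence
#'
#' Band-passes the signal to the high (amplitude) band, takes the analytic
#' signal magnitude as the time-varying energy envelope, and computes the
#' magnitude-squared coherence between that envelope and the raw signal,
#' averaged over the low (phase) band's frequencies.  Values lie in
#' `[0, 1]`; an envelope phase-locked to a low-band component in the raw
#' signal drives the value up.
#'
#' @param x Numeric vector (several cycles of the low band).
#' @param fs Sampling rate (Hz).
#' @param low_band,high_band Band names from [band_scheme()] (low in
#'   delta/theta) or explicit `(low, high)` Hz ranges.
#' @param scheme A [band_scheme()].
#' @return Coupling value in `[0, 1]`.
#' @export
phase_amplitude_coupling <- function(x, fs, low_band = "theta",
                                     high_band = "betaH",
                                     scheme = band_scheme()) {
  if (var(x) == 0) stop("degenerate (constant) input")
  lb <- if (is.character(low_band)) scheme$bands[[low_band]] else low_band
  hb <- if (is.character(high_band)) scheme$bands[[high_band]] else high_band
  if (is.null(lb) || is.null(hb)) stop("unknown band name")
  filt <- butter_bandpass(hb[1], min(hb[2], fs / 2 * 0.99), fs, order = 4)
  env <- Mod(analytic_signal(sos_filtfilt(filt, x)))
  coh <- coherence_spectrum(x, env, fs)
  sel <- coh$freq >= lb[1] & coh$freq < lb[2]
  mean(coh$coh[sel])
}

# analytic signal via frequency-domain Hilbert transformer
analytic_signal <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Welch magnitude-squared coherence (Hann, 1-s segments, 50% overlap)
coherence_spectrum <- function(x, y, fs, seg_seconds = 1, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, as.integer(round(fs * seg_seconds)))
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)
  if (length(starts) < 2)
    warning("coherence from fewer than 2 segments is degenerate")
  w <- hann_window(seg)
  segmat <- function(v) vapply(starts, function(s) {
    vi <- v[s:(s + seg - 1L)]
    (vi - mean(vi)) * w
  }, numeric(seg))
  X <- mvfft(segmat(x))
  Y <- mvfft(segmat(y))
  nf <- seg %/% 2 + 1
  X <- X[seq_len(nf), , drop = FALSE]
  Y <- Y[seq_len(nf), , drop = FALSE]
  pxx <- rowMeans(Mod(X)^2)
  pyy <- rowMeans(Mod(Y)^2)
  pxy <- rowMeans(X * Conj(Y))
  coh <- Mod(pxy)^2 / (pxx * pyy)
  coh[!is.finite(coh)] <- 0
  list(freq = (seq_len(nf) - 1) * fs / seg, coh = coh)
}
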