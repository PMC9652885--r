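# Subject-level candidate-feature table.
#
# Per channel (39 features): APSD and RPSD in the 9 sub-bands, 14
# phase-amplitude couplings ({delta, theta} phase x 7 amplitude bands), 3
# Hjorth parameters, Shannon entropy, Lyapunov exponent, Hurst exponent,
# Lempel-Ziv complexity.  Per symmetric pair (18): DASM and RASM in the 9
# sub-bands.  Full 32-channel montage: 39*32 + 18*14 = 1500 columns.
# Every feature is computed per 5-s epoch and averaged across the
# subject's epochs.

#' Candidate-feature column names for a channel set
#'
#' @param channels Character vector of channel labels present.
#' @param montage An `eeg_montage`; pairs wholly inside `channels` get
#'   DASM/RASM columns.
#' @param scheme A [band_scheme()].
#' @return Character vector of feature names, channel-major then pair-major,
#'   e.g. `"RPSD_alphaH_F3"`, `"PAC_theta-betaH_P8"`, `"DASM_delta_FC5-FC6"`.
#' @export
feature_names <- function(channels, montage = montage_32(),
                          scheme = band_scheme()) {
  bn <- names(scheme$bands)
  pac <- as.vector(t(outer(scheme$pac_low, scheme$pac_high, paste, sep = "-")))
  per_ch <- function(ch) c(
    paste0("APSD_", bn, "_", ch),
    paste0("RPSD_", bn, "_", ch),
    paste0("PAC_", pac, "_", ch),
    paste0(c("HjorthActivity_", "HjorthMobility_", "HjorthComplexity_"), ch),
    paste0(c("SE_", "LE_", "HE_", "KC_"), ch))
  pairs <- montage$pairs[montage$pairs[, 1] %in% channels &
                           montage$pairs[, 2] %in% channels, , drop = FALSE]
  per_pair <- function(l, r) c(paste0("DASM_", bn, "_", l, "-", r),
                               paste0("RASM_", bn, "_", l, "-", r))
  c(unlist(lapply(channels, per_ch)),
    if (nrow(pairs) > 0)
      unlist(lapply(seq_len(nrow(pairs)),
                    function(i) per_pair(pairs[i, 1], pairs[i, 2]))))
}

# Precomputed spectral machinery shared across epochs/channels of one
# sampling-rate / epoch-length combination.
feature_context <- function(fs, nsamp, scheme, params) {
  seg <- min(nsamp, as.integer(round(fs)))   # 1-s Welch segments
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, nsamp - seg + 1L, by = step)
  w <- hann_window(seg)
  nf <- seg %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / seg
  df <- fs / seg
  band_mask <- lapply(scheme$bands, function(b) freq >= b[1] & freq < b[2])
  total_mask <- freq >= scheme$total[1] & freq < scheme$total[2]
  dbl <- rep(2, nf); dbl[1] <- 1; if (seg %% 2 == 0) dbl[nf] <- 1
  pac_filt <- lapply(scheme$pac_high, function(nm) {
    b <- scheme$bands[[nm]]
    butter_bandpass(b[1], min(b[2], 0.99 * fs / 2), fs, order = 4)
  })
  names(pac_filt) <- scheme$pac_high
  hilb <- rep(0, nsamp)
  if (nsamp %% 2 == 0) {
    hilb[1] <- 1; hilb[nsamp / 2 + 1] <- 1; hilb[2:(nsamp / 2)] <- 2
  } else {
    hilb[1] <- 1; hilb[2:((nsamp + 1) / 2)] <- 2
  }
  idx <- outer(seq_len(seg), starts - 1L, `+`)   # seg x nseg sample index
  list(fs = fs, nsamp = nsamp, seg = seg, starts = starts, nseg =
         length(starts), idx = idx, w = w, nf = nf,
       freq = freq, df = df, band_mask = band_mask, total_mask = total_mask,
       dbl = dbl, pac_filt = pac_filt, hilb = hilb,
       sumw2 = sum(w^2), scheme = scheme, params = params)
}

# Hann-windowed, per-segment-demeaned segment FFT.  `x` may be a matrix of
# signals (columns); segments of all signals are batched into one mvfft.
# Returns nf x (nseg * nsignal), segment-major within signal.
segment_fft <- function(x, ctx) {
  x <- as.matrix(x)
  A <- matrix(x[as.vector(ctx$idx) + rep((seq_len(ncol(x)) - 1L) * ctx$nsamp,
                                         each = length(ctx$idx))],
              nrow = ctx$seg)
  A <- (A - rep(colMeans(A), each = ctx$seg)) * ctx$w
  mvfft(A)[seq_len(ctx$nf), , drop = FALSE]
}

# all per-channel features of one epoch; returns list(feat, apsd)
epoch_channel_features <- function(x, ctx) {
  p <- ctx$params
  X <- segment_fft(x, ctx)
  pxx <- rowMeans(Mod(X)^2)
  psd <- ctx$dbl * pxx / (ctx$fs * ctx$sumw2)
  apsd <- vapply(ctx$band_mask, function(m) sum(psd[m]) * ctx$df, numeric(1))
  total <- sum(psd[ctx$total_mask]) * ctx$df
  if (total <= 0) stop("degenerate signal: zero total-band power")
  rpsd <- apsd / total
  # PAC: high-band envelopes vs raw, coherence averaged over low bands;
  # all 7 Hilbert transforms and all envelope segment FFTs batched
  pac <- matrix(NA_real_, 2, length(ctx$pac_filt))
  low_masks <- ctx$band_mask[ctx$scheme$pac_low]
  BP <- vapply(ctx$pac_filt, function(fl) sos_filtfilt(fl, x),
               numeric(ctx$nsamp))
  ENV <- Mod(mvfft(mvfft(BP) * ctx$hilb, inverse = TRUE) / ctx$nsamp)
  Yall <- segment_fft(ENV, ctx)
  for (j in seq_along(ctx$pac_filt)) {
    Y <- Yall[, ((j - 1) * ctx$nseg + 1):(j * ctx$nseg), drop = FALSE]
    pyy <- rowMeans(Mod(Y)^2)
    pxy <- rowMeans(X * Conj(Y))
    coh <- Mod(pxy)^2 / (pxx * pyy)
    coh[!is.finite(coh)] <- 0
    pac[1, j] <- mean(coh[low_masks[[1]]])
    pac[2, j] <- mean(coh[low_masks[[2]]])
  }
  hj <- hjorth(x)
  feat <- c(apsd, rpsd, as.vector(t(pac)), hj,
            shannon_entropy(x, p$entropy_bins),
            lyapunov_exponent(x, ctx$fs, p),
            hurst_exponent(x, p$hurst_window_sizes),
            lempel_ziv_complexity(x, p$lz_binarize))
  list(feat = feat, apsd = apsd)
}

#' Build the subject-level candidate-feature table
#'
#' Computes all ten feature families per epoch and channel, derives the
#' pair asymmetry features from the per-epoch band powers, and averages
#' each feature across the subject's epochs.
#'
#' @param epoch_sets List of [epoch_set()] objects with identical channel
#'   sets, sampling rates and epoch counts.
#' @param montage An `eeg_montage`.
#' @param params A [nonlinear_params()].
#' @param scheme A [band_scheme()].
#' @param verbose Print one line per subject.
#' @return A `feature_table`: data.frame with `subject_id`, `group` and one
#'   numeric column per feature (1500 for the full montage).
#' @export
build_feature_table <- function(epoch_sets, montage = montage_32(),
                                params = nonlinear_params(),
                                scheme = band_scheme(), verbose = FALSE) {
  stopifnot(length(epoch_sets) >= 1)
  ref <- epoch_sets[[1]]
  channels <- ref$channel_labels
  if (!all(channels %in% montage$channels))
    stop("unknown channel label(s): ",
         paste(setdiff(channels, montage$channels), collapse = ", "))
  for (es in epoch_sets) {
    if (!identical(es$channel_labels, channels) || es$fs != ref$fs ||
        !identical(dim(es$data), dim(ref$data)))
      stop("epoch set for ", es$subject_id,
           " does not match the cohort layout (channels/fs/epoch count)")
  }
  pairs <- montage$pairs[montage$pairs[, 1] %in% channels &
                           montage$pairs[, 2] %in% channels, , drop = FALSE]
  cols <- feature_names(channels, montage, scheme)
  ctx <- feature_context(ref$fs, dim(ref$data)[3], scheme, params)
  n_band <- length(scheme$bands)
  n_perch <- 39L
  rows <- matrix(NA_real_, length(epoch_sets), length(cols))
  for (si in seq_along(epoch_sets)) {
    es <- epoch_sets[[si]]
    n_ep <- dim(es$data)[1]
    acc <- matrix(0, n_ep, length(cols))
    for (e in seq_len(n_ep)) {
      apsd_ch <- matrix(NA_real_, length(channels), n_band)
      for (ci in seq_along(channels)) {
        r <- epoch_channel_features(es$data[e, ci, ], ctx)
        acc[e, ((ci - 1) * n_perch + 1):(ci * n_perch)] <- r$feat
        apsd_ch[ci, ] <- r$apsd
      }
      if (nrow(pairs) > 0) {
        off <- length(channels) * n_perch
        for (pi in seq_len(nrow(pairs))) {
          li <- match(pairs[pi, 1], channels)
          ri <- match(pairs[pi, 2], channels)
          asym <- asymmetry(apsd_ch[li, ], apsd_ch[ri, ])
          acc[e, off + ((pi - 1) * 2 * n_band + 1):((pi - 1) * 2 * n_band +
                                                      2 * n_band)] <-
            c(asym$dasm, asym$rasm)
        }
      }
    }
    rows[si, ] <- colMeans(acc)
    if (verbose)
      message("features: ", es$subject_id, " (", si, "/",
              length(epoch_sets), ")")
  }
  out <- data.frame(subject_id = vapply(epoch_sets, `[[`, "", "subject_id"),
                    group = vapply(epoch_sets, `[[`, "", "group"),
                    rows, stringsAsFactors = FALSE)
  names(out) <- c("subject_id", "group", cols)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Restrict a feature table to an electrode configuration
#'
#' Keeps per-channel features for channels in the configuration and
#' DASM/RASM features only for pairs wholly inside it; the retained column
#' count is `39 * n_electrodes + 18 * n_pairs`.
#'
#' @param table A `feature_table`.
#' @param config An [electrode_configuration()] or a character vector of
#'   electrode labels (pairs inferred from the montage).
#' @param montage An `eeg_montage`.
#' @return The restricted `feature_table`.
#' @export
restrict_features <- function(table, config, montage = montage_32()) {
  electrodes <- if (inherits(config, "electrode_config")) config$electrodes
  else config
  if (!all(electrodes %in% montage$channels))
    stop("unknown channel(s) in configuration: ",
         paste(setdiff(electrodes, montage$channels), collapse = ", "))
  cols <- setdiff(names(table), c("subject_id", "group"))
  suffix <- sub(".*_", "", cols)
  keep <- suffix %in% electrodes |
    (grepl("-", suffix) &
       vapply(strsplit(suffix, "-"), function(p) all(p %in% electrodes),
              logical(1)) &
       grepl("^(DASM|RASM)_", cols))
  out <- table[, c("subject_id", "group", cols[keep]), drop = FALSE]
  class(out) <- class(table)
  out
}
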