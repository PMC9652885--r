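#' Preprocessing parameters
#'
#' Defaults mirror a standard resting-state pipeline: 0.5-50 Hz band-pass
#' (6th-order zero-phase Butterworth), 5-s non-overlapping epochs, rejection
#' of any epoch whose maximal absolute potential on any channel exceeds
#' 75 uV, and random subsampling to exactly 20 clean epochs per subject.
#'
#' @param band Numeric length-2, band-pass edges in Hz.
#' @param filter_order Butterworth design order (applied forward-backward,
#'   so the effective magnitude roll-off is twice this order; set 3 for an
#'   effective 6th-order magnitude response).
#' @param epoch_seconds Epoch length in seconds.
#' @param reject_threshold_uv Amplitude rejection threshold in microvolts.
#' @param epochs_per_subject Number of epochs retained per subject.
#' @param rng_seed Seed controlling the random epoch subsample.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(band = c(0.5, 50), filter_order = 6,
                              epoch_seconds = 5, reject_threshold_uv = 75,
                              epochs_per_subject = 20, rng_seed = 1L) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            epochs_per_subject >= 1, epoch_seconds > 0,
            reject_threshold_uv > 0)
  structure(list(band = band, filter_order = as.integer(filter_order),
                 epoch_seconds = epoch_seconds,
                 reject_threshold_uv = reject_threshold_uv,
                 epochs_per_subject = as.integer(epochs_per_subject),
                 rng_seed = rng_seed),
            class = "preprocess_params")
}

#' Baseline-correct and band-pass filter a continuous recording
#'
#' Subtracts the per-channel mean, then applies the zero-phase Butterworth
#' band-pass channel by channel.
#'
#' @param raw Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param params A [preprocess_params()].
#' @return Filtered matrix of the same shape.
#' @export
preprocess_continuous <- function(raw, fs, params = preprocess_params()) {
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = 1)
  if (!all(is.finite(raw))) stop("non-finite values in raw recording")
  if (fs <= 2 * params$band[2])
    stop("sampling rate ", fs, " Hz too low for band up to ",
         params$band[2], " Hz")
  filt <- butter_bandpass(params$band[1], params$band[2], fs,
                          order = params$filter_order)
  centered <- raw - rowMeans(raw)
  out <- t(apply(centered, 1, function(ch) sos_filtfilt(filt, ch)))
  dimnames(out) <- dimnames(raw)
  out
}

#' Cut a continuous recording into non-overlapping epochs
#'
#' @param filtered Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param epoch_seconds Epoch length (s).
#' @return Array `epochs x channels x samples`; the trailing remainder that
#'   does not fill a whole epoch is discarded.
#' @export
segment_epochs <- function(filtered, fs, epoch_seconds = 5) {
  if (!is.matrix(filtered)) filtered <- matrix(filtered, nrow = 1)
  len <- as.integer(round(fs * epoch_seconds))
  n <- ncol(filtered)
  n_ep <- n %/% len
  if (n_ep < 1) stop("recording shorter than one epoch (", epoch_seconds, " s)")
  out <- array(0, dim = c(n_ep, nrow(filtered), len))
  for (e in seq_len(n_ep))
    out[e, , ] <- filtered[, ((e - 1) * len + 1):(e * len), drop = FALSE]
  dimnames(out) <- list(NULL, rownames(filtered), NULL)
  out
}

#' Reject high-amplitude epochs and subsample to a fixed count
#'
#' An epoch is rejected when the maximal absolute potential on any channel
#' exceeds the threshold.  From the surviving epochs, exactly
#' `epochs_per_subject` are drawn uniformly at random under `rng_seed`
#' (deterministic for a fixed seed); the retained epochs keep their
#' original temporal order.
#'
#' @param epochs Array `epochs x channels x samples`.
#' @param params A [preprocess_params()].
#' @param subject_id Used in error messages.
#' @return Array with exactly `epochs_per_subject` epochs.
#' @export
reject_and_subsample <- function(epochs, params = preprocess_params(),
                                 subject_id = "subject") {
  thr <- params$reject_threshold_uv
  peak <- apply(abs(epochs), 1, max)
  keep <- which(peak <= thr)
  if (length(keep) < params$epochs_per_subject)
    stop("insufficient clean epochs for ", subject_id, ": ", length(keep),
         " survive the ", thr, " uV criterion, ", params$epochs_per_subject,
         " required")
  sel <- with_seed(params$rng_seed,
                   sample(keep, params$epochs_per_subject))
  epochs[sort(sel), , , drop = FALSE]
}

#' Bundle one subject's preprocessed epochs
#'
#' @param subject_id Character scalar.
#' @param group `"MCI"` or `"HC"`.
#' @param data Array `epochs x channels x samples`, microvolts, finite.
#' @param fs Sampling rate (Hz).
#' @param channel_labels Channel labels matching `dim(data)[2]`, in montage
#'   order (the full 32 channels or a declared subset).
#' @return An `epoch_set`.
#' @export
epoch_set <- function(subject_id, group, data, fs, channel_labels) {
  group <- match.arg(group, c("MCI", "HC"))
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[2] == length(channel_labels))
  if (!all(is.finite(data))) stop("non-finite values in epoch data for ",
                                  subject_id)
  structure(list(subject_id = subject_id, group = group, data = data,
                 fs = fs, channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", x$subject_id, " [", x$group, "] ",
      d[1], " epochs x ", d[2], " channels x ", d[3], " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Run the full preprocessing chain on one continuous recording
#'
#' Baseline correction, zero-phase band-pass, epoching, amplitude-based
#' rejection and random subsampling, bundled as an [epoch_set()].
#'
#' @inheritParams preprocess_continuous
#' @inheritParams epoch_set
#' @return An `epoch_set`.
#' @export
preprocess_subject <- function(raw, fs, channel_labels, subject_id, group,
                               params = preprocess_params()) {
  filtered <- preprocess_continuous(raw, fs, params)
  ep <- segment_epochs(filtered, fs, params$epoch_seconds)
  ep <- reject_and_subsample(ep, params, subject_id)
  epoch_set(subject_id, group, ep, fs, channel_labels)
}
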