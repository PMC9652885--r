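# Minimal EDF (European Data Format) I/O for continuous uniform-rate
# recordings, plus a plain container for epoch sets (flat little-endian
# float64 tensor + JSON sidecar).  The EDF subset implemented here covers
# the standard continuous case: one fixed record duration, identical
# sampling rate across signals, 16-bit samples with per-signal physical
# scaling.  No DSP/EEG I/O package exists in the target R environment, so
# this is implemented in-package and round-trip tested.

pad <- function(x, width) formatC(as.character(x), width = width,
                                  flag = "-")

#' Write a continuous recording to an EDF file
#'
#' @param path Output file.
#' @param data Channels x samples numeric matrix (physical units, uV).
#' @param fs Sampling rate (Hz); records are 1 s long, the recording is
#'   truncated to a whole number of records.
#' @param labels Channel labels (default from rownames).
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, data, fs, labels = rownames(data),
                      patient = "X", recording = "synthetic") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  ns <- nrow(data)
  labels <- labels %||% paste0("CH", seq_len(ns))
  spr <- as.integer(round(fs))          # samples per 1-s record
  n_rec <- ncol(data) %/% spr
  stopifnot(n_rec >= 1)
  data <- data[, seq_len(n_rec * spr), drop = FALSE]
  # physical range floored/ceiled to 2 decimals: always covers the data
  # (no clamping) and prints exactly in the 8-character ASCII header field
  pmin_ <- floor(apply(data, 1, min) * 100) / 100
  pmax_ <- ceiling(apply(data, 1, max) * 100) / 100
  if (any(abs(c(pmin_, pmax_)) >= 10000))
    stop("physical values too large for the EDF header encoding")
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad("0", 8), pad(patient, 80), pad(recording, 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(hdr_bytes, 8),
    pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4)),
    con, eos = NULL)
  field <- function(values, width)
    writeChar(paste(vapply(values, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(formatC(pmin_, format = "f", digits = 2), 8)
  field(formatC(pmax_, format = "f", digits = 2), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                       # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - pmin_[s]) / scale[s]) + dmin
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Supports the standard continuous case with a uniform sampling rate
#' across signals.
#'
#' @param path EDF file.
#' @return List with `data` (channels x samples, physical units), `fs`,
#'   `labels`, `n_records`, `record_seconds`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i)
    trimws(rd(width)), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)                                  # phys dim
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (s in seq_len(ns))
      data[s, cols] <- (block[((s - 1) * spr[1] + 1):(s * spr[1])] -
                          dmin[s]) * scale[s] + pmin_[s]
  }
  rownames(data) <- labels
  list(data = data, fs = fs, labels = labels, n_records = n_rec,
       record_seconds = rec_dur)
}

#' Write an epoch set as a flat binary tensor plus JSON sidecar
#'
#' @param es An [epoch_set()].
#' @param dir Output directory (created if needed); files are
#'   `<subject_id>.bin` (float64, little-endian, epoch-major) and
#'   `<subject_id>.json`.
#' @return The sidecar path, invisibly.
#' @export
write_epoch_set <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, es$subject_id)
  con <- file(paste0(base, ".bin"), "wb")
  writeBin(as.numeric(aperm(es$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  close(con)
  meta <- list(subject_id = es$subject_id, group = es$group, fs = es$fs,
               channel_labels = es$channel_labels,
               epochs = dim(es$data)[1],
               epoch_seconds = dim(es$data)[3] / es$fs)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  invisible(paste0(base, ".json"))
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param sidecar Path to the `.json` sidecar.
#' @return An [epoch_set()].
#' @export
read_epoch_set <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- as.integer(round(meta$fs * meta$epoch_seconds))
  nch <- length(meta$channel_labels)
  con <- file(sub("\\.json$", ".bin", sidecar), "rb")
  raw <- readBin(con, "numeric", n = n * nch * meta$epochs, size = 8,
                 endian = "little")
  close(con)
  data <- aperm(array(raw, dim = c(n, nch, meta$epochs)), c(3, 2, 1))
  epoch_set(meta$subject_id, meta$group, data, meta$fs, meta$channel_labels)
}
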