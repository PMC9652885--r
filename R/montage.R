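#' The 32-channel modified 10-20 montage
#'
#' Returns the montage used throughout the package: 32 scalp electrodes of
#' the modified 10-20 system, decomposed into the 4 midline electrodes
#' (their own mirror images) and the 14 left/right symmetric pairs, plus
#' the electrode subsets of five commercial wearable EEG devices.
#'
#' @return An object of class `eeg_montage` with elements
#'   `channels` (ordered character vector of 32 labels),
#'   `midline` (character vector of 4),
#'   `pairs` (14 x 2 character matrix, columns `left`/`right`),
#'   `device_montages` (named list of electrode-label vectors).
#' @examples
#' m <- montage_32()
#' nrow(m$pairs)        # 14 symmetric pairs
#' m$device_montages$Focusband
#' @export
montage_32 <- function() {
  pairs <- matrix(c(
    "Fp1", "Fp2",
    "AF3", "AF4",
    "F7",  "F8",
    "F3",  "F4",
    "FC5", "FC6",
    "FC1", "FC2",
    "T7",  "T8",
    "C3",  "C4",
    "CP5", "CP6",
    "CP1", "CP2",
    "P7",  "P8",
    "P3",  "P4",
    "PO3", "PO4",
    "O1",  "O2"), ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("left", "right")))
  midline <- c("Fz", "Cz", "Pz", "Oz")
  channels <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                "PO3", "PO4", "O1", "Oz", "O2")
  device_montages <- list(
    Focusband = c("Fp1", "Fp2"),
    Insight   = c("Pz", "AF3", "AF4", "T7", "T8"),
    DSI7      = c("Pz", "F3", "F4", "C3", "C4", "P3", "P4"),
    Imec      = c("Fz", "Cz", "F7", "F8", "F3", "F4", "C3", "C4"),
    EPOC      = c("AF3", "AF4", "F7", "F8", "F3", "F4", "FC5", "FC6",
                  "T7", "T8", "P7", "P8", "O1", "O2"))
  m <- structure(list(channels = channels, midline = midline, pairs = pairs,
                      device_montages = device_montages),
                 class = "eeg_montage")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  stopifnot(length(m$channels) == 32,
            length(m$midline) + 2L * nrow(m$pairs) == length(m$channels),
            all(c(m$pairs) %in% m$channels),
            all(m$midline %in% m$channels),
            anyDuplicated(m$channels) == 0,
            anyDuplicated(c(m$pairs, m$midline)) == 0)
  for (dm in m$device_montages) stopifnot(all(dm %in% m$channels))
  invisible(m)
}

#' Construct a bilaterally symmetric electrode configuration
#'
#' A configuration is a set of electrodes built from whole symmetric pairs
#' (a pair is in or out atomically) and individual midline electrodes.
#'
#' @param pairs Character vector of pair identifiers, e.g. `"FC5-FC6"`, or
#'   left-member labels, e.g. `"FC5"`.
#' @param midline Character vector of midline labels (subset of Fz, Cz, Pz, Oz).
#' @param montage An `eeg_montage`.
#' @return An `electrode_config` with elements `electrodes` (in montage
#'   order), `pairs_used` (pair ids), `midline_used`.
#' @examples
#' electrode_configuration("F3-F4", "Fz")
#' @export
electrode_configuration <- function(pairs = character(),
                                    midline = character(),
                                    montage = montage_32()) {
  pair_ids <- paste(montage$pairs[, 1], montage$pairs[, 2], sep = "-")
  idx <- match(pairs, pair_ids)
  miss <- is.na(idx)
  idx[miss] <- match(pairs[miss], montage$pairs[, 1])
  if (anyNA(idx))
    stop("unknown symmetric pair(s): ", paste(pairs[is.na(idx)], collapse = ", "))
  if (!all(midline %in% montage$midline))
    stop("unknown midline electrode(s): ",
         paste(setdiff(midline, montage$midline), collapse = ", "))
  if (anyDuplicated(idx) || anyDuplicated(midline))
    stop("duplicated electrodes in configuration")
  electrodes <- c(t(montage$pairs[idx, , drop = FALSE]), midline)
  electrodes <- montage$channels[sort(match(electrodes, montage$channels))]
  structure(list(electrodes = electrodes,
                 pairs_used = pair_ids[sort(idx)],
                 midline_used = montage$midline[sort(match(midline, montage$midline))]),
            class = "electrode_config")
}

#' @export
format.electrode_config <- function(x, ...) {
  paste(x$electrodes, collapse = "-")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat("<electrode_config> ", format(x), "  (", length(x$pairs_used),
      " pair(s), ", length(x$midline_used), " midline)\n", sep = "")
  invisible(x)
}

#' Enumerate all bilaterally symmetric configurations of a given size
#'
#' Every configuration of exactly `k` electrodes formed by whole symmetric
#' pairs plus midline electrodes.  The count is
#' \eqn{\sum_{2p+m=k} \binom{14}{p}\binom{4}{m}}: 20, 176, 924 and 3276 for
#' k = 2, 4, 6 and 8.
#'
#' @param k Total electrode count, 1..32.
#' @param montage An `eeg_montage`.
#' @return List of `electrode_config`, in lexicographic order of the
#'   selected atoms (pairs in montage pair order, then midline electrodes).
#' @examples
#' length(enumerate_configurations(2))  # 20
#' @export
enumerate_configurations <- function(k, montage = montage_32()) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > 32)
    stop("k must be a single integer in 1..32")
  n_pairs <- nrow(montage$pairs)
  n_mid <- length(montage$midline)
  pair_ids <- paste(montage$pairs[, 1], montage$pairs[, 2], sep = "-")
  out <- list()
  keys <- character()
  for (p in 0:min(n_pairs, k %/% 2)) {
    m <- k - 2L * p
    if (m < 0 || m > n_mid) next
    pc <- if (p > 0) combn(n_pairs, p, simplify = FALSE) else list(integer())
    mc <- if (m > 0) combn(n_mid, m, simplify = FALSE) else list(integer())
    for (ps in pc) for (ms in mc) {
      out[[length(out) + 1L]] <- electrode_configuration(
        pairs = pair_ids[ps], midline = montage$midline[ms],
        montage = montage)
      # atom index key: pairs are atoms 1..14, midline 15..18
      keys[length(keys) + 1L] <-
        paste(sprintf("%02d", c(ps, ms + n_pairs)), collapse = ",")
    }
  }
  out[order(keys)]
}
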