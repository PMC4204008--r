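# Preprocessing: bring any input signal to the analysis clock
# (256 Hz, 0.16-50 Hz) and cut it into 30-s epochs of fifteen
# non-overlapping 2-s subepochs aligned to the hypnogram.

TARGET_FS <- 256
EPOCH_SECONDS <- 30
SUBEPOCH_SECONDS <- 2

#' Resample an EEG record to 256 Hz
#'
#' Rational-ratio polyphase resampling (via [signal::resample()]) with
#' the built-in anti-aliasing low-pass. A record already at 256 Hz is
#' returned unchanged.
#'
#' @param record An [eeg_record()].
#' @param target_fs Target sampling rate in Hz (default 256).
#' @return An [eeg_record()] at `target_fs`.
#' @export
resample_to_256 <- function(record, target_fs = TARGET_FS) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (record$fs == target_fs) return(record)
  frac <- ratio_integers(target_fs / record$fs)
  out <- signal::resample(record$samples, p = frac[1], q = frac[2])
  n_expect <- round(length(record$samples) * target_fs / record$fs)
  out <- out[seq_len(min(length(out), n_expect))]
  eeg_record(out, fs = target_fs, channel = record$channel)
}

# smallest p/q with p/q == x (to within tol), for rational resampling
ratio_integers <- function(x, tol = 1e-9, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < tol) return(c(as.integer(round(p)), q))
  }
  stop("cannot express resampling ratio ", x, " as a small fraction",
       call. = FALSE)
}

#' Band-limit an EEG record
#'
#' Applies the analysis front-end filters: a first-order Butterworth
#' high-pass at 0.16 Hz (DC removal) followed by a second-order
#' Butterworth low-pass at 50 Hz. Both are applied causally in a single
#' forward pass, as a real-time system would.
#'
#' @param record An [eeg_record()] at 256 Hz.
#' @param hp_hz High-pass cutoff (Hz, default 0.16).
#' @param lp_hz Low-pass cutoff (Hz, default 50).
#' @return The filtered [eeg_record()].
#' @export
bandlimit <- function(record, hp_hz = 0.16, lp_hz = 50) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$fs != TARGET_FS) {
    stop("bandlimit() expects a 256 Hz record; call resample_to_256() first",
         call. = FALSE)
  }
  nyq <- record$fs / 2
  hp <- signal::butter(1, hp_hz / nyq, type = "high")
  lp <- signal::butter(2, lp_hz / nyq, type = "low")
  x <- signal::filter(hp, record$samples)
  x <- signal::filter(lp, x)
  eeg_record(as.numeric(x), fs = record$fs, channel = record$channel)
}

#' Segment a record into 30-s epochs aligned to a hypnogram
#'
#' Cuts the signal into consecutive non-overlapping 30-s epochs starting
#' at sample 0, each made of fifteen contiguous 2-s subepochs (512
#' samples at 256 Hz). A trailing partial epoch is discarded. If the
#' signal and hypnogram disagree on the epoch count, both are truncated
#' to the shorter with a warning.
#'
#' @param record An [eeg_record()] at 256 Hz.
#' @param hyp Optional [hypnogram()] to align with.
#' @return An object of class `epoch_grid`: list with `epochs` (a list
#'   of numeric vectors of 7680 samples), `stages` (aligned labels or
#'   `NULL`), `fs`, `subepochs_per_epoch` and `subepoch_samples`.
#' @export
segment <- function(record, hyp = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$fs != TARGET_FS) {
    stop("segment() expects a 256 Hz record", call. = FALSE)
  }
  epoch_len <- EPOCH_SECONDS * record$fs
  sub_len <- SUBEPOCH_SECONDS * record$fs
  n_total <- length(record$samples)
  n_epochs <- n_total %/% epoch_len
  if (n_epochs < 1) {
    stop("recording shorter than one 30-s epoch", call. = FALSE)
  }
  dropped <- n_total - n_epochs * epoch_len
  if (dropped > 0) {
    warning(sprintf("discarding trailing partial epoch (%.1f s)",
                    dropped / record$fs), call. = FALSE)
  }
  stages <- NULL
  if (!is.null(hyp)) {
    stopifnot(inherits(hyp, "hypnogram"))
    if (length(hyp) != n_epochs) {
      warning(sprintf(
        "signal has %d epochs but hypnogram has %d; truncating to %d",
        n_epochs, length(hyp), min(n_epochs, length(hyp))), call. = FALSE)
      n_epochs <- min(n_epochs, length(hyp))
    }
    stages <- hyp$stages[seq_len(n_epochs)]
  }
  epochs <- lapply(seq_len(n_epochs), function(i) {
    record$samples[((i - 1) * epoch_len + 1):(i * epoch_len)]
  })
  structure(list(epochs = epochs, stages = stages, fs = record$fs,
                 subepochs_per_epoch = epoch_len %/% sub_len,
                 subepoch_samples = sub_len),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epochs x %d subepochs x %d samples @ %g Hz\n",
              length(x$epochs), x$subepochs_per_epoch, x$subepoch_samples,
              x$fs))
  invisible(x)
}

#' Full preprocessing front end
#'
#' Convenience wrapper: resample to 256 Hz, band-limit, segment.
#'
#' @inheritParams segment
#' @param record An [eeg_record()] at any sampling rate.
#' @return An `epoch_grid` (see [segment()]).
#' @export
preprocess <- function(record, hyp = NULL) {
  segment(bandlimit(resample_to_256(record)), hyp)
}
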