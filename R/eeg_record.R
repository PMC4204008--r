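#' Construct an EEG record
#'
#' A uniformly sampled single-channel EEG signal with its sampling rate
#' and channel label. This is the container every processing step in the
#' package consumes and returns.
#'
#' @param samples Numeric vector of signal samples (microvolts).
#' @param fs Sampling rate in Hz; must be positive.
#' @param channel Channel label, e.g. `"Fp1-A2"`.
#' @return An object of class `eeg_record`: a list with elements
#'   `samples`, `fs` and `channel`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * seq(0, 1, by = 1 / 256)), fs = 256)
#' duration(rec)
#' @export
eeg_record <- function(samples, fs, channel = "EEG") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(samples)) {
    stop("`samples` must be numeric", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         channel = as.character(channel)[1L]),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, duration(x)))
  invisible(x)
}

#' Duration of an EEG record in seconds
#'
#' @param record An [eeg_record()].
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$fs
}
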