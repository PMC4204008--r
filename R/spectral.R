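# Spectral features per 30-s epoch: SEF50/SEF95 per 2-s subepoch, their
# mean difference SEFd (smoothed across epochs), and absolute/relative
# band power in dB. All features work on one-sided 512-point FFT
# magnitude spectra with 0.5 Hz resolution.

#' Frequency-band configuration
#'
#' A closed frequency interval aligned to the 0.5 Hz FFT bin grid. The
#' analysis default is 8-16 Hz, where REM shows reduced alpha/sigma
#' power with a rise near 15 Hz, so the spectral edge frequencies
#' spread apart.
#'
#' @param f1,f2 Band edges in Hz; `0 <= f1 < f2 <= 128`, both multiples
#'   of 0.5. Edges are inclusive.
#' @return An object of class `band_config`.
#' @export
band_config <- function(f1 = 8, f2 = 16) {
  if (!(f1 >= 0 && f1 < f2 && f2 <= 128)) {
    stop("band edges must satisfy 0 <= f1 < f2 <= 128", call. = FALSE)
  }
  if (any(abs(c(f1, f2) * 2 - round(c(f1, f2) * 2)) > 1e-9)) {
    stop("band edges must align to the 0.5 Hz bin grid", call. = FALSE)
  }
  structure(list(f1 = f1, f2 = f2), class = "band_config")
}

band_bins <- function(spec, band) {
  which(spec$freq >= band$f1 - 1e-9 & spec$freq <= band$f2 + 1e-9)
}

#' One-sided magnitude spectrum of a 2-s subepoch
#'
#' 512-point FFT of a 512-sample subepoch at 256 Hz after mean removal
#' (no taper window). Returns the 257 one-sided magnitude bins on the
#' 0, 0.5, ..., 128 Hz grid. With this convention the time-domain
#' energy of the mean-removed subepoch equals
#' `(mag[1]^2 + 2*sum(mag[2:256]^2) + mag[257]^2) / 512`
#' (see [spectrum_energy()]).
#'
#' @param x Numeric vector of exactly 512 samples.
#' @return Object of class `subepoch_spectrum`: list with `mag`
#'   (magnitudes), `freq` (Hz) and `n_bins` (257).
#' @export
compute_spectrum <- function(x) {
  if (length(x) != 512L) {
    stop("subepoch must have exactly 512 samples", call. = FALSE)
  }
  x <- x - mean(x)
  X <- stats::fft(x)
  mag <- Mod(X)[1:257]
  structure(list(mag = mag, freq = seq(0, 128, by = 0.5), n_bins = 257L),
            class = "subepoch_spectrum")
}

#' Time-domain energy implied by a one-sided spectrum
#'
#' Applies the one-sided scaling documented in [compute_spectrum()]:
#' interior bins count twice, DC and Nyquist once, divided by the
#' transform length. Equals `sum((x - mean(x))^2)` of the source
#' subepoch up to floating-point error.
#'
#' @param spec A `subepoch_spectrum`.
#' @return Energy (sum of squared mean-removed samples).
#' @export
spectrum_energy <- function(spec) {
  m2 <- spec$mag^2
  (m2[1] + 2 * sum(m2[2:256]) + m2[257]) / 512
}

#' Spectral edge frequency within a band
#'
#' The lowest in-band bin frequency below which the given fraction of
#' the in-band signal power (squared magnitudes) is contained: the
#' smallest `x` with cumulative power at `x` at least
#' `fraction * total`. `fraction = 0.5` gives the band median frequency
#' (SEF50), `0.95` gives SEF95.
#'
#' @param spec A `subepoch_spectrum` from [compute_spectrum()].
#' @param fraction Power fraction in (0, 1).
#' @param band A [band_config()].
#' @return Edge frequency in Hz, or `NA_real_` if the band power is
#'   zero (undefined feature; callers mark the epoch invalid).
#' @export
compute_sef <- function(spec, fraction, band = band_config()) {
  stopifnot(inherits(spec, "subepoch_spectrum"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  bins <- band_bins(spec, band)
  p <- spec$mag[bins]^2
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  x <- which(cumsum(p) >= fraction * total)[1]
  spec$freq[bins[x]]
}

#' Per-epoch spectral edge frequency difference (SEFd)
#'
#' The mean over the fifteen 2-s subepochs of `SEF95 - SEF50`. REM
#' epochs in the 8-16 Hz band show a low band-median frequency together
#' with a high 95% edge, so this difference peaks during REM.
#'
#' @param sef_pairs Numeric matrix with 15 rows and columns `sef50`,
#'   `sef95` (one row per subepoch), as produced internally by
#'   [extract_features()].
#' @return SEFd in Hz, or `NA_real_` if any subepoch is invalid.
#' @export
compute_sefd_epoch <- function(sef_pairs) {
  stopifnot(is.matrix(sef_pairs), ncol(sef_pairs) == 2L)
  if (nrow(sef_pairs) != 15L) {
    stop("an epoch must contribute exactly 15 subepoch SEF pairs",
         call. = FALSE)
  }
  if (anyNA(sef_pairs)) return(NA_real_)
  mean(sef_pairs[, 2] - sef_pairs[, 1])
}

#' Smooth a per-epoch SEFd series
#'
#' Centered 9-point moving average across epochs. Near the series ends
#' the window shrinks symmetrically, so constants are preserved and the
#' output has the input's length. `NA` entries (invalid epochs) are
#' skipped in each window mean and stay `NA` in the output.
#'
#' @param x Numeric per-epoch SEFd series.
#' @param width Odd window width (default 9).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_sefd <- function(x, width = 9) {
  stopifnot(is.numeric(x), width >= 1, width %% 2 == 1)
  n <- length(x)
  if (n == 0) return(x)
  half <- (width - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    if (is.na(x[i])) return(NA_real_)
    w <- x[(i - h):(i + h)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
  out
}

# 20*log10 of the band magnitude sum for one subepoch; NA if sum == 0
subepoch_ap <- function(spec, bins) {
  s <- sum(spec$mag[bins])
  if (s <= 0) return(NA_real_)
  20 * log10(s)
}

#' Absolute band power of an epoch (dB)
#'
#' Per subepoch, `20 * log10` of the sum of in-band FFT magnitudes;
#' the epoch value is the mean over the fifteen subepochs.
#'
#' @param spectra List of 15 `subepoch_spectrum` objects.
#' @param band A [band_config()].
#' @return AP in dB, or `NA_real_` if any subepoch has zero band
#'   magnitude sum.
#' @export
compute_ap_epoch <- function(spectra, band = band_config()) {
  stopifnot(length(spectra) == 15L)
  bins <- band_bins(spectra[[1]], band)
  vals <- vapply(spectra, subepoch_ap, numeric(1), bins = bins)
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Relative band power of an epoch (dB)
#'
#' Per subepoch, `20 * log10` of the ratio of the in-band magnitude sum
#' to the full-spectrum magnitude sum (DC bin excluded, up to Nyquist);
#' the epoch value is the mean over the fifteen subepochs. Always
#' non-positive when the band is a subset of the full spectrum.
#'
#' @inheritParams compute_ap_epoch
#' @return RP in dB, or `NA_real_` if any subepoch has zero total
#'   magnitude sum.
#' @export
compute_rp_epoch <- function(spectra, band = band_config()) {
  stopifnot(length(spectra) == 15L)
  bins <- band_bins(spectra[[1]], band)
  vals <- vapply(spectra, function(sp) {
    num <- sum(sp$mag[bins])
    den <- sum(sp$mag[-1])   # exclude DC
    if (den <= 0 || num <= 0) return(NA_real_)
    20 * log10(num / den)
  }, numeric(1))
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Extract per-epoch features from an epoch grid
#'
#' Runs the full feature pipeline over a segmented recording: per 2-s
#' subepoch a 512-point FFT; per epoch SEFd (subsequently smoothed
#' across epochs with a 9-point moving average), AP and RP in the
#' configured band. Epochs whose band power vanishes in any subepoch
#' are flagged invalid (`valid = FALSE`, features `NA`) and are treated
#' as non-REM downstream.
#'
#' @param grid An `epoch_grid` from [segment()].
#' @param band A [band_config()] (default 8-16 Hz).
#' @param smooth_width Moving-average width for the SEFd series
#'   (default 9).
#' @return A data.frame of class `epoch_features` with columns `epoch`,
#'   `sefd` (smoothed, Hz), `sefd_raw` (Hz), `ap` (dB), `rp` (dB),
#'   `valid`, and `stage` (reference label, `NA` if the grid carries
#'   none).
#' @export
extract_features <- function(grid, band = band_config(), smooth_width = 9) {
  stopifnot(inherits(grid, "epoch_grid"))
  n <- length(grid$epochs)
  if (n == 0) stop("empty epoch grid", call. = FALSE)
  sub_len <- grid$subepoch_samples
  nsub <- grid$subepochs_per_epoch
  sefd_raw <- ap <- rp <- rep(NA_real_, n)
  for (e in seq_len(n)) {
    xs <- grid$epochs[[e]]
    spectra <- lapply(seq_len(nsub), function(s) {
      compute_spectrum(xs[((s - 1) * sub_len + 1):(s * sub_len)])
    })
    pairs <- t(vapply(spectra, function(sp) {
      c(compute_sef(sp, 0.50, band), compute_sef(sp, 0.95, band))
    }, numeric(2)))
    colnames(pairs) <- c("sef50", "sef95")
    sefd_raw[e] <- compute_sefd_epoch(pairs)
    ap[e] <- compute_ap_epoch(spectra, band)
    rp[e] <- compute_rp_epoch(spectra, band)
  }
  valid <- !is.na(sefd_raw) & !is.na(ap) & !is.na(rp)
  out <- data.frame(
    epoch = seq_len(n),
    sefd = smooth_sefd(sefd_raw, smooth_width),
    sefd_raw = sefd_raw,
    ap = ap,
    rp = rp,
    valid = valid,
    stage = if (is.null(grid$stages)) NA_character_ else grid$stages,
    stringsAsFactors = FALSE
  )
  class(out) <- c("epoch_features", "data.frame")
  out
}
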