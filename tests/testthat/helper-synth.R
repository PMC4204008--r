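# Shared fixtures: synthetic recordings and their feature tables are
# expensive enough to cache across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

synth_features <- function(seed, n_epochs = 100) {
  key <- sprintf("fx_%d_%d", seed, n_epochs)
  if (is.null(.fixture_cache[[key]])) {
    sr <- synthesize_recording(sleep_stage_sequence(n_epochs), seed = seed)
    grid <- preprocess(sr$record, sr$hypnogram)
    .fixture_cache[[key]] <- extract_features(grid)
  }
  .fixture_cache[[key]]
}

# a pure tone record, handy for spectral checks
tone_record <- function(freq_hz, fs = 256, seconds = 10, amp = 1) {
  t <- (seq_len(fs * seconds) - 1) / fs
  eeg_record(amp * cos(2 * pi * freq_hz * t), fs = fs)
}

# a spectrum with prescribed magnitudes at the 8-16 Hz bins, zeros
# elsewhere (bins on the 0.5 Hz grid; band_values has 17 entries)
band_spectrum <- function(band_values, elsewhere = 0) {
  mag <- rep(elsewhere, 257)
  freq <- seq(0, 128, by = 0.5)
  mag[freq >= 8 & freq <= 16] <- band_values
  structure(list(mag = mag, freq = freq, n_bins = 257L),
            class = "subepoch_spectrum")
}

# brute-force SEF oracle: linear scan over cumulative band power
sef_oracle <- function(mag, freq, fraction, f1 = 8, f2 = 16) {
  keep <- freq >= f1 & freq <= f2
  p <- mag[keep]^2
  f <- freq[keep]
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  acc <- 0
  for (i in seq_along(p)) {
    acc <- acc + p[i]
    if (acc >= fraction * tot) return(f[i])
  }
  f[length(f)]
}

# brute-force AUC oracle: pairwise concordance with ties counted half
auc_oracle <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
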