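test_that("subepoch spectrum has the documented geometry and energy", {
  zero <- compute_spectrum(rep(0, 512))
  expect_equal(zero$n_bins, 257L)
  expect_equal(zero$freq, seq(0, 128, by = 0.5))
  expect_true(all(zero$mag == 0))

  # bin-aligned 12 Hz unit cosine: one dominant bin, clean elsewhere
  t <- (0:511) / 256
  spec <- compute_spectrum(cos(2 * pi * 12 * t))
  peak <- which.max(spec$mag)
  expect_equal(spec$freq[peak], 12)
  others <- spec$mag[-c(peak - 1, peak, peak + 1)]
  expect_lt(max(others), 1e-9 * spec$mag[peak])

  # Parseval identity under the documented one-sided scaling
  set.seed(7)
  x <- rnorm(512)
  sp <- compute_spectrum(x)
  expect_equal(spectrum_energy(sp), sum((x - mean(x))^2),
               tolerance = 1e-6)

  expect_error(compute_spectrum(rnorm(100)), "512")
})

test_that("spectral edge frequency matches hand-derived cases", {
  # all power in the 12 Hz bin
  one <- band_spectrum(c(rep(0, 8), 10, rep(0, 8)))
  expect_equal(compute_sef(one, 0.5), 12)
  expect_equal(compute_sef(one, 0.95), 12)

  # uniform power across the 17 band bins: 50% first reached at the
  # 9th bin (12 Hz), 95% at the 17th (16 Hz)
  flat <- band_spectrum(rep(1, 17))
  expect_equal(compute_sef(flat, 0.5), 12)
  expect_equal(compute_sef(flat, 0.95), 16)

  # zero band power: undefined
  expect_true(is.na(compute_sef(band_spectrum(rep(0, 17)), 0.5)))
})

test_that("compute_sef agrees with the brute-force cumulative oracle", {
  set.seed(11)
  for (i in 1:50) {
    mag <- rep(0, 257)
    mag[sample(257, 40)] <- runif(40, 0, 5)
    spec <- structure(list(mag = mag, freq = seq(0, 128, 0.5), n_bins = 257L),
                      class = "subepoch_spectrum")
    for (fr in c(0.5, 0.95, runif(1, 0.05, 0.95))) {
      expect_identical(compute_sef(spec, fr),
                       sef_oracle(mag, spec$freq, fr))
    }
  }
})

test_that("SEF is monotone: in fraction, and under high-bin power", {
  set.seed(13)
  for (i in 1:25) {
    vals <- runif(17, 0, 3)
    spec <- band_spectrum(vals)
    s50 <- compute_sef(spec, 0.5)
    s95 <- compute_sef(spec, 0.95)
    expect_gte(s95, s50)

    # adding power only above the current SEF never lowers it
    above <- which(seq(8, 16, 0.5) > s50)
    if (length(above) > 0) {
      vals2 <- vals
      vals2[above] <- vals2[above] + runif(length(above), 0, 2)
      expect_gte(compute_sef(band_spectrum(vals2), 0.5), s50)
    }
  }
})

test_that("per-epoch SEFd is the mean of subepoch differences", {
  pairs <- cbind(sef50 = rep(10, 15), sef95 = rep(12, 15))
  expect_equal(compute_sefd_epoch(pairs), 2)

  d <- c(rep(0.5, 8), rep(1.0, 7))
  pairs <- cbind(rep(10, 15), 10 + d)
  expect_equal(compute_sefd_epoch(pairs), 11 / 15)

  pairs[3, 1] <- NA
  expect_true(is.na(compute_sefd_epoch(pairs)))
  expect_error(compute_sefd_epoch(cbind(1:10, 1:10)), "15")
})

test_that("9-point SEFd smoothing preserves constants and spreads impulses", {
  expect_equal(smooth_sefd(rep(3.2, 40)), rep(3.2, 40))
  expect_equal(smooth_sefd(5), 5)

  x <- rep(0, 41); x[21] <- 1
  out <- smooth_sefd(x)
  expect_equal(out[17:25], rep(1 / 9, 9))
  expect_equal(out[c(1:16, 26:41)], rep(0, 32))
  expect_length(out, 41)
})

test_that("absolute and relative band power follow the dB formulas", {
  single <- band_spectrum(c(10, rep(0, 16)))
  spectra <- rep(list(single), 15)
  expect_equal(compute_ap_epoch(spectra), 20)

  flat <- band_spectrum(rep(1, 17))
  expect_equal(compute_ap_epoch(rep(list(flat), 15)), 20 * log10(17))

  # all non-DC power in the band: RP = 0 dB
  expect_equal(compute_rp_epoch(rep(list(flat), 15)), 0)

  # band sum exactly half of the full-spectrum sum
  half <- band_spectrum(rep(1, 17), elsewhere = 0)
  half$mag[half$freq >= 20 & half$freq <= 28] <- 17 / 17
  expect_equal(sum(half$mag[half$freq >= 8 & half$freq <= 16]) /
                 sum(half$mag[-1]), 0.5)
  expect_equal(compute_rp_epoch(rep(list(half), 15)), 20 * log10(0.5))

  zero <- band_spectrum(rep(0, 17))
  expect_true(is.na(compute_ap_epoch(rep(list(zero), 15))))
  expect_true(is.na(compute_rp_epoch(rep(list(zero), 15))))
})

test_that("RP never exceeds 0 dB on random spectra", {
  set.seed(17)
  for (i in 1:20) {
    mag <- runif(257, 0, 2)
    spec <- structure(list(mag = mag, freq = seq(0, 128, 0.5), n_bins = 257L),
                      class = "subepoch_spectrum")
    expect_lte(compute_rp_epoch(rep(list(spec), 15)), 0)
  }
})

test_that("feature extraction preserves order, smoothing and validity", {
  # three identical epochs: identical rows, smoothing is identity
  t <- (0:7679) / 256
  epoch <- cos(2 * pi * 10 * t) + 0.5 * cos(2 * pi * 14 * t)
  grid <- structure(list(epochs = rep(list(epoch), 3), stages = NULL,
                         fs = 256, subepochs_per_epoch = 15L,
                         subepoch_samples = 512L), class = "epoch_grid")
  fx <- extract_features(grid)
  expect_equal(nrow(fx), 3)
  expect_equal(fx$sefd, rep(fx$sefd[1], 3))
  expect_equal(fx$sefd, fx$sefd_raw)
  expect_true(all(fx$valid))

  # an all-zero epoch is invalid; neighbours keep their features
  grid$epochs[[2]] <- rep(0, 7680)
  fx2 <- extract_features(grid)
  expect_equal(fx2$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(fx2$sefd[2]))
  expect_equal(fx2$sefd_raw[c(1, 3)], fx$sefd_raw[c(1, 3)])
})

test_that("REM epochs show higher SEFd than N2 through the full pipeline", {
  fx <- synth_features(301)
  expect_gt(mean(fx$sefd_raw[fx$stage == "REM"]),
            mean(fx$sefd_raw[fx$stage == "N2"]))
  expect_gt(median(fx$sefd_raw[fx$stage == "REM"]) -
              median(fx$sefd_raw[fx$stage != "REM"]), 0)
})
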