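test_that("default templates satisfy the stage-contrast constraints", {
  tpl <- default_templates()
  expect_setequal(names(tpl), c("W", "N1", "N2", "N3", "REM"))

  band_amp <- function(t, lo, hi) {
    mean(t$bin_amplitudes[t$freq >= lo & t$freq <= hi])
  }
  # REM spindle-range (12-14 Hz) amplitude strictly below N2's
  expect_lt(band_amp(tpl$REM, 12, 14), band_amp(tpl$N2, 12, 14))
  # REM 9-15 Hz amplitude below every non-REM template
  for (s in c("W", "N1", "N2", "N3")) {
    expect_lt(band_amp(tpl$REM, 9, 15), band_amp(tpl[[s]], 9, 15))
  }
  # REM shows a local rise near 15-16 Hz relative to its 12-14 Hz floor
  expect_gt(band_amp(tpl$REM, 15, 16), 2 * band_amp(tpl$REM, 12, 14))
  # Wake and N1 carry more total 8-16 Hz power than REM
  pow <- function(t) sum(t$bin_amplitudes[t$freq >= 8 & t$freq <= 16]^2)
  expect_gt(pow(tpl$W), pow(tpl$REM))
  expect_gt(pow(tpl$N1), pow(tpl$REM))
  # all templates carry band power
  for (t in tpl) expect_gt(pow(t), 0)
  # N3 is delta-dominated
  expect_gt(band_amp(tpl$N3, 0.5, 4), 3 * band_amp(tpl$N3, 8, 16))
})

test_that("analytic template SEFd is greatest for REM", {
  tpl <- default_templates()
  sefd <- vapply(tpl, function(t) template_sef(t)["sefd"], numeric(1))
  expect_equal(names(which.max(sefd)), "REM")
  expect_true(all(sefd[c("W", "N1", "N2", "N3")] < sefd["REM"]))
})

test_that("epoch synthesis is deterministic and spectrally faithful", {
  tpl <- default_templates()$REM
  x1 <- synthesize_epoch(tpl, seed = 5)
  x2 <- synthesize_epoch(tpl, seed = 5)
  expect_length(x1, 7680)
  expect_identical(x1, x2)
  expect_false(identical(x1, synthesize_epoch(tpl, seed = 6)))

  # averaged subepoch FFT magnitudes track the template in-band
  specs <- lapply(1:15, function(s) {
    compute_spectrum(x1[((s - 1) * 512 + 1):(s * 512)])$mag
  })
  avg <- Reduce(`+`, specs) / 15
  freq <- seq(0, 128, 0.5)
  inband <- freq >= 8 & freq <= 16
  want <- tpl$bin_amplitudes[tpl$freq >= 8 & tpl$freq <= 16]
  expect_gt(cor(avg[inband], want), 0.9)
})

test_that("recording synthesis matches the requested stage sequence", {
  hyp <- hypnogram(c("W", "N2", "REM", "N2", "W"))
  sr <- synthesize_recording(hyp, seed = 3)
  expect_equal(duration(sr$record), 150)
  expect_equal(sr$record$fs, 256)
  expect_equal(sr$hypnogram$stages, hyp$stages)

  sr2 <- synthesize_recording(hyp, seed = 4)
  expect_false(identical(sr$record$samples, sr2$record$samples))
  expect_equal(sr2$hypnogram$stages, hyp$stages)

  expect_error(
    synthesize_recording(hyp, templates = default_templates()["W"]),
    "no template")
})

test_that("measured REM SEFd stochastically dominates non-REM", {
  fx <- synth_features(307)
  rem <- fx$sefd_raw[fx$stage == "REM"]
  oth <- fx$sefd_raw[fx$stage != "REM"]
  expect_gte(length(rem), 25)
  expect_gt(median(rem) - median(oth), 0)
  # strong separation, not a marginal effect
  expect_gt(quantile(rem, 0.1), quantile(oth, 0.9))
})

test_that("the default stage sequence is REM-flanked-by-N2 and sized right", {
  hyp <- sleep_stage_sequence(100)
  expect_length(hyp, 100)
  st <- hyp$stages
  rem <- which(st == "REM")
  expect_gt(length(rem), 20)
  neighbours <- setdiff(c(rem - 1, rem + 1), rem)
  neighbours <- neighbours[neighbours >= 1 & neighbours <= 100]
  expect_true(all(st[neighbours] == "N2"))
})
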