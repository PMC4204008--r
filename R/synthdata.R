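# Stage-labelled synthetic single-channel EEG. Each sleep stage is a
# spectral template: target magnitudes on the 0.5 Hz bin grid over
# 0.5-50 Hz, built from a 1/f background plus Gaussian bumps. Signals
# are synthesized as sums of bin-aligned random-phase sinusoids, so the
# measured subepoch FFT reproduces the template almost exactly and the
# feature pipeline can be tested against analytic expectations.

synth_bins <- function() seq(0.5, 50, by = 0.5)

gauss_bump <- function(f, center, height, width) {
  height * exp(-((f - center)^2) / (2 * width^2))
}

#' Construct a stage template
#'
#' @param stage Canonical stage label.
#' @param bg_scale Amplitude scale of the 1/f background.
#' @param bg_exponent Power-law exponent of the background power
#'   spectrum (amplitude falls as `f^(-bg_exponent/2)`).
#' @param bumps Data.frame with columns `center`, `height`, `width`
#'   (Hz / amplitude / Hz) of Gaussian spectral peaks.
#' @param jitter Relative amplitude noise applied per subepoch.
#' @param scale Overall amplitude scale. The default puts the absolute
#'   band power of the synthesized stages in the same dB range as the
#'   shipped classifier defaults, so the fixed threshold profile is
#'   meaningful on synthetic recordings too.
#' @return Object of class `stage_template` with `stage`, `freq`,
#'   `bin_amplitudes` and `jitter`.
#' @export
stage_template <- function(stage, bg_scale, bg_exponent, bumps,
                           jitter = 0.15, scale = 1 / 600) {
  f <- synth_bins()
  amp <- bg_scale * f^(-bg_exponent / 2)
  for (i in seq_len(nrow(bumps))) {
    amp <- amp + gauss_bump(f, bumps$center[i], bumps$height[i],
                            bumps$width[i])
  }
  amp <- amp * scale
  stopifnot(all(amp >= 0))
  structure(list(stage = stage, freq = f, bin_amplitudes = amp,
                 jitter = jitter),
            class = "stage_template")
}

#' Default spectral templates for the five sleep stages
#'
#' The templates encode the discriminative band-power phenomenology of
#' sleep EEG in the 8-16 Hz band: REM has reduced 9-15 Hz power with a
#' rise near 15-16 Hz (so its 8-16 Hz spectral edges spread apart);
#' Wake and N1 carry more total 8-16 Hz power (alpha and mixed
#' activity); N2 concentrates band power in the 12-14 Hz spindle range;
#' N3 is dominated by 0.5-4 Hz delta with only a weak slow-spindle
#' remnant in-band. Numeric values are artifact parameters chosen to
#' satisfy these orderings, not measurements of real EEG.
#'
#' @return Named list of [stage_template()] objects for `W`, `N1`,
#'   `N2`, `N3`, `REM`.
#' @export
default_templates <- function() {
  list(
    W = stage_template("W", bg_scale = 2.0, bg_exponent = 1.0, data.frame(
      center = c(10.0, 20.0), height = c(6.0, 1.0), width = c(1.0, 3.0))),
    N1 = stage_template("N1", bg_scale = 1.5, bg_exponent = 1.0, data.frame(
      center = c(6.0, 10.5), height = c(3.0, 2.5), width = c(1.2, 1.5))),
    N2 = stage_template("N2", bg_scale = 1.2, bg_exponent = 1.2, data.frame(
      center = c(1.5, 13.0), height = c(6.0, 4.0), width = c(1.0, 1.2))),
    N3 = stage_template("N3", bg_scale = 1.2, bg_exponent = 1.2, data.frame(
      center = c(1.5, 12.5), height = c(25.0, 5.0), width = c(1.2, 0.6))),
    REM = stage_template("REM", bg_scale = 0.5, bg_exponent = 1.0, data.frame(
      center = c(5.5, 8.0, 15.75), height = c(2.0, 3.0, 2.4),
      width = c(1.0, 0.4, 0.35)))
  )
}

#' Analytic spectral edge frequencies of a template
#'
#' Computes SEF50, SEF95 and their difference directly from the
#' template bin amplitudes (squared as power, cumulative sum over the
#' in-band bins), without synthesizing any signal. This is the closed
#' form the measured features should approach as jitter goes to zero.
#'
#' @param template A [stage_template()].
#' @param band A [band_config()].
#' @return Named vector `sef50`, `sef95`, `sefd` (Hz).
#' @export
template_sef <- function(template, band = band_config()) {
  stopifnot(inherits(template, "stage_template"))
  inband <- template$freq >= band$f1 - 1e-9 & template$freq <= band$f2 + 1e-9
  f <- template$freq[inband]
  p <- template$bin_amplitudes[inband]^2
  tot <- sum(p)
  edge <- function(fr) f[which(cumsum(p) >= fr * tot)[1]]
  s50 <- edge(0.50); s95 <- edge(0.95)
  c(sef50 = s50, sef95 = s95, sefd = s95 - s50)
}

# cached cos/sin bases for bin-aligned synthesis (512 x n_bins)
synth_cache <- new.env(parent = emptyenv())

synth_basis <- function(fs, n_samples) {
  key <- sprintf("%g_%d", fs, n_samples)
  if (!is.null(synth_cache[[key]])) return(synth_cache[[key]])
  t <- (seq_len(n_samples) - 1) / fs
  f <- synth_bins()
  arg <- 2 * pi * outer(t, f)
  basis <- list(cosm = cos(arg), sinm = sin(arg))
  synth_cache[[key]] <- basis
  basis
}

synthesize_subepoch <- function(template, basis) {
  nb <- length(template$bin_amplitudes)
  a <- template$bin_amplitudes *
    pmax(1 + template$jitter * stats::rnorm(nb), 0)
  phi <- stats::runif(nb, 0, 2 * pi)
  # sum_b a_b cos(2 pi f_b t + phi_b)
  as.numeric(basis$cosm %*% (a * cos(phi)) - basis$sinm %*% (a * sin(phi)))
}

#' Synthesize one 30-s epoch for a stage template
#'
#' Fifteen 2-s subepochs at 256 Hz, each a sum of bin-aligned
#' sinusoids with per-subepoch jittered template amplitudes and
#' uniform random phases. Deterministic for a fixed seed.
#'
#' @param template A [stage_template()].
#' @param seed Optional integer seed.
#' @return Numeric vector of 7680 samples.
#' @export
synthesize_epoch <- function(template, seed = NULL) {
  stopifnot(inherits(template, "stage_template"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  basis <- synth_basis(256, 512)
  unlist(lapply(1:15, function(s) synthesize_subepoch(template, basis)))
}

#' Synthesize a stage-labelled EEG recording
#'
#' Concatenates one synthetic 30-s epoch per hypnogram label.
#'
#' @param hyp A [hypnogram()] (or character vector of stage labels)
#'   giving the stage of each epoch. `UNSCORED`/`MOVEMENT` epochs are
#'   synthesized from the Wake template.
#' @param templates Named list of [stage_template()] objects covering
#'   every stage in `hyp`.
#' @param seed Integer seed; the whole recording is deterministic
#'   given the seed.
#' @param channel Channel label for the returned record.
#' @return List with `record` (an [eeg_record()] at 256 Hz) and
#'   `hypnogram` (the input labels as a [hypnogram()]).
#' @export
synthesize_recording <- function(hyp, templates = default_templates(),
                                 seed = 1, channel = "synthEEG") {
  if (!inherits(hyp, "hypnogram")) hyp <- hypnogram(hyp)
  if (length(hyp) == 0) stop("stage sequence must be non-empty", call. = FALSE)
  stages <- hyp$stages
  lookup <- stages
  lookup[lookup %in% c("UNSCORED", "MOVEMENT")] <- "W"
  missing <- setdiff(unique(lookup), names(templates))
  if (length(missing) > 0) {
    stop("no template for stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- unlist(lapply(lookup, function(s) {
    synthesize_epoch(templates[[s]])
  }))
  list(record = eeg_record(samples, fs = 256, channel = channel),
       hypnogram = hyp)
}

#' A plausible whole-night stage sequence
#'
#' A deterministic sleep-cycle pattern (wake, descent through N1/N2/N3,
#' two REM periods flanked by N2) recycled to the requested length.
#' Used as the default labelling for synthetic recordings; REM periods
#' are bordered by N2 on both sides, as in typical adult sleep
#' architecture.
#'
#' @param n_epochs Number of 30-s epochs (default 100).
#' @return A [hypnogram()].
#' @export
sleep_stage_sequence <- function(n_epochs = 100) {
  cycle <- c(rep("W", 3), rep("N1", 4), rep("N2", 14), rep("N3", 12),
             rep("N2", 6), rep("REM", 15), rep("N2", 10), rep("N3", 8),
             rep("N2", 8), rep("REM", 15), rep("N2", 3), rep("W", 2))
  stages <- rep(cycle, length.out = n_epochs)
  hypnogram(stages)
}
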