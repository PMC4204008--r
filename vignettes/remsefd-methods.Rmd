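---
title: "Detecting REM sleep from one EEG channel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting REM sleep from one EEG channel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remsefd)
```

## The problem

Scoring rapid-eye-movement (REM) sleep normally requires EOG and EMG
channels alongside the EEG, because REM and light sleep (N1) look alike
on a single EEG trace. For wearable and home sleep-staging systems the
extra electrodes are the main obstacle, and so is computational cost:
battery-powered devices cannot afford large feature sets or neural
network classifiers. `remsefd` implements a deliberately minimal
detector that scores REM epochs from a single EEG channel using three
spectral features and four fixed thresholds.

## Features

The signal is analyzed at 256 Hz in standard 30-s epochs, each split
into fifteen non-overlapping 2-s subepochs. Every subepoch is
transformed with a 512-point FFT (0.5 Hz resolution, one-sided
magnitudes $|\mathrm{mag}_i|$).

**Spectral edge frequencies.** $SEF_{xx}$ is the lowest frequency below
which $xx\%$ of the signal power lies. Within a band $[f_1, f_2]$ we
take the smallest bin frequency $x$ with

$$\sum_{i \le x} |\mathrm{mag}_i|^2 \;\ge\; \frac{xx}{100}
  \sum_{i \in [f_1,f_2]} |\mathrm{mag}_i|^2 .$$

$SEF_{50}$ is the band median frequency, $SEF_{95}$ the 95% edge.

**SEFd.** The discriminating feature is the per-epoch mean of the
subepoch edge spreads,

$$SEFd(e) = \frac{1}{15}\sum_{n=1}^{15}
  \left(SEF_{95}[se_n] - SEF_{50}[se_n]\right),$$

followed by a 9-point moving average across epochs. In the 8–16 Hz
band, REM sleep combines two effects: power between 9 and 15 Hz is
depressed relative to all other stages, while activity rises again
near 15–16 Hz. The band median therefore drops toward 8 Hz while the
95% edge is dragged up toward 16 Hz, and their difference peaks during
REM — in wake (alpha near 10 Hz), N2 (spindles at 12–14 Hz) and N3
(delta dominance, little in-band structure) the in-band power is more
concentrated and the spread stays small.

**Band powers.** Absolute power
$AP = 20\log_{10}\sum_{band} |\mathrm{mag}_i|$ and relative power
$RP = 20\log_{10}\left(\sum_{band}|\mathrm{mag}_i| \big/
\sum_{all}|\mathrm{mag}_i|\right)$, each computed per subepoch and
averaged over the epoch. Both operate on magnitude sums (not squared
power); the dB values follow that literal convention. AP is lowest in
REM within 8–16 Hz (wake and N1 are distinctly higher), and RP
occupies a stable mid range, so the pair separates REM from wake-like
false positives that pass the SEFd stage.

## The two-stage classifier

With thresholds $(SEFd_{th}, AP_{max}, RP_{max}, RP_{min})$:

1. **Stage 1 (sensitive):** an epoch is a *candidate* REM epoch iff
   $SEFd \ge SEFd_{th}$. Non-candidates are rejected immediately and
   their AP/RP never need computing — the source of the method's low
   computational cost.
2. **Stage 2 (specific):** a candidate is accepted as REM iff
   $AP \le AP_{max}$ and $RP_{min} \le RP \le RP_{max}$.

All inequalities are inclusive. Epochs with vanishing band power carry
no defined features and are scored non-REM (fail-safe). The shipped
default profile is `rem_thresholds()`: 4.54 Hz, 15.5 dB, and
[−13.03, −6.08] dB.

## Preprocessing choices

* Input signals are resampled to 256 Hz by rational-ratio polyphase
  filtering (`signal::resample`), with its anti-alias low-pass.
* Band-limiting uses a first-order Butterworth high-pass at 0.16 Hz
  (DC removal) and a second-order Butterworth low-pass at 50 Hz. Both
  run causally in a single forward pass: the method targets real-time
  wearable use, where zero-phase double filtering is unavailable, and
  at 30-s epoch granularity the group delay is immaterial.
* Epochs start at sample 0; a trailing partial epoch is discarded. If
  signal and hypnogram disagree on epoch count, both are truncated to
  the shorter with a warning.
* Subepochs are transformed without a taper window, after subtracting
  the subepoch mean. Mean removal keeps residual DC (the high-pass
  transient) from leaking into the lowest bins; a rectangular window
  keeps bin-aligned content exactly on the 0.5 Hz grid, which the
  synthetic generator exploits.

## Numerical conventions

* Band edges are inclusive: "8–16 Hz" is the closed interval, 17 bins
  on the 0.5 Hz grid.
* The cumulative SEF rule resolves ties to the *lower* frequency (the
  smallest bin reaching the fraction).
* The RP denominator is the one-sided spectrum excluding the DC bin,
  up to Nyquist.
* Only SEFd is smoothed across epochs; AP and RP are epoch means only.
  Near the ends of the series the 9-point window shrinks
  symmetrically, so constants are preserved and length is unchanged;
  invalid (`NA`) epochs are skipped inside each window and remain `NA`
  themselves.
* Metric percentages with zero denominators (e.g. selectivity with no
  REM detections) are reported `NA`, never 0, so averages over
  recordings are not silently deflated.
* Cohen's kappa is computed on the binary REM/non-REM task — the
  detector is binary; a multi-class agreement would be a property of a
  different system.
* `MOVEMENT` reference epochs count as Wake for evaluation (AASM
  convention), `UNSCORED` epochs are excluded; both policies are
  configurable in `run_config()`.

## Threshold calibration

Stage 1 sweeps the decision threshold over the observed smoothed SEFd
values (rule: value ≥ threshold is positive), builds the ROC curve,
integrates AUC trapezoidally (equal to the pairwise concordance
probability), and picks the operating point closest to the (0, 1)
corner — equal weight to sensitivity and specificity. Distance ties go
to the higher-specificity point, then to the lower threshold, making
the result deterministic.

Stage 2 searches `ap_max` over quantiles of the candidate epochs' AP
values and `(rp_min, rp_max)` over quantile pairs of their RP values
(41 grid points per parameter by default), scoring each triple by the
same distance-to-(0,1) objective computed over *all* epochs. Each grid
additionally contains the option of leaving a bound inactive
(`±Inf`). This matters: when stage 1 already separates the training
data perfectly, every bound placed at the exact observed extremum of
the candidates would clip unseen recordings while removing no training
false positive. Ties are therefore broken toward higher specificity
and then toward the wider acceptance region, so a stage-2 bound is
only placed where it actually rejects false positives in training.

`crossvalidate()` partitions *recordings* (subjects), never epochs,
into k folds, calibrates on the pooled training epochs and evaluates
frozen thresholds on the held-out subjects; the fold assignment is
seeded and reproducible.

An optional per-recording calibration (run `calibrate_thresholds()`
per subject and summarize the spread) is available by mapping over
recordings; the default path is a single fixed profile for all
subjects, which is what a zero-configuration wearable would use.

## The synthetic generator

Real overnight PSG databases cannot be bundled, so the package
generates stage-labelled EEG whose *band-power structure* reproduces
the phenomenology the detector relies on. Each stage is a spectral
template on the 0.5 Hz grid over 0.5–50 Hz: a $1/f$ background plus
Gaussian bumps —

* **W**: strong alpha near 10 Hz, elevated broadband power;
* **N1**: theta near 6 Hz plus moderate mixed 10–12 Hz activity;
* **N2**: a 12–14 Hz spindle-band elevation over a modest background;
* **N3**: dominant 0.5–4 Hz delta with only a weak slow-spindle
  remnant in-band;
* **REM**: reduced 9–15 Hz amplitude, with in-band power concentrated
  at the 8 Hz edge and a distinct rise near 15.5–16 Hz.

Epochs are synthesized as sums of bin-aligned sinusoids with
per-subepoch jittered amplitudes (15% relative noise) and uniform
random phases. Bin alignment with the 512-point FFT makes the
template-to-spectrum mapping near exact, so analytic expectations
computed directly from template amplitudes (`template_sef()`) are
tight oracles for the measured pipeline. The overall amplitude scale
places the synthetic stages' AP in the same dB range as the shipped
default thresholds, so the fixed profile is directly usable on
synthetic recordings.

The default whole-night labelling (`sleep_stage_sequence()`) is a
deterministic sleep-cycle pattern with REM periods of fifteen epochs
flanked by N2 — typical adult architecture, and deliberately so: the
9-point SEFd smoothing mixes each REM bout edge with its N2
neighbours, producing a ramp between the N2 SEFd level (≈1.5 Hz
measured) and the REM level (≈7.3 Hz). The template geometry is chosen
so that the lowest smoothed REM value — the boundary a
distance-optimal ROC calibration recovers — sits at ≈4.5 Hz, matching
the field-reported operating point for this feature. Calibration runs
on independently seeded synthetic nights recover the threshold within
±0.25 Hz.

What the generator does **not** emulate: movement and muscle
artefacts, electrode pops, non-stationarity within a stage, inter-
subject variability of band positions, or realistic absolute EEG
amplitudes (template values are artifact parameters satisfying the
ordering constraints, not µV measurements). Passing the end-to-end
synthetic tests therefore demonstrates the correctness of the
machinery and the internal consistency of the method — not clinical
performance, which can only be established on real PSG databases read
through the same EDF interface.

## Problem sizes in the test suite

The bundled studies use 100-epoch (50-minute) synthetic nights with
about 30 REM epochs each: one calibration night and one independent
detection night for the end-to-end check, and twenty independently
seeded nights for the boundary-recovery study. These sizes give stable
order statistics for the recovered threshold while keeping the whole
suite fast enough to run routinely.

## Known limitations

* EDF support is the minimal subset needed here: 16-bit EDF/EDF+
  signals and TAL stage annotations; no discontinuous (EDF+D) files,
  no per-signal transducer metadata round-trip.
* The detector has no contextual smoothing of the predicted hypnogram
  (e.g. "no isolated single REM epochs" rules); adding rules would
  change the sensitivity/specificity balance and is out of scope.
* Fixed thresholds are a population compromise; per-subject
  calibration is known to improve selectivity substantially and is
  supported but not the default.
* With very short recordings (tens of epochs) the stage-2 quantile
  grids become coarse; calibration then mostly reduces to stage 1.
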