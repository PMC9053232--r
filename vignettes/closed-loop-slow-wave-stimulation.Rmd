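---
title: "Closed-loop auditory slow-wave stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop auditory slow-wave stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoloop)
```

somnoloop is a desk-scale simulator and analysis toolkit for closed-loop
phase-targeted auditory stimulation of sleep slow waves. A wearable device of
this kind listens to one frontal EEG channel in real time, decides when the
sleeper is in stable deep NREM sleep, estimates the instantaneous phase of
the ongoing slow oscillation, and plays short pink-noise bursts timed to the
depolarized "up-phase" of the wave, with the aim of enhancing slow-wave
activity (SWA). Because raw trial recordings of such systems are generally
not public, the package pairs the device logic with a synthetic
polysomnography generator with known ground truth, so every stage of the
pipeline can be exercised and verified end to end.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not show about real data.

## The synthetic polysomnography model

One night is a single EEG channel (Fpz-A2-like), sampled at 250 Hz in uV,
assembled from:

* **Slow oscillation.** A frequency-wandering sinusoid: the instantaneous
  frequency follows an Ornstein-Uhlenbeck process (relaxation time 10 s,
  stationary SD 0.12 Hz) around the center of the 0.75--1.25 Hz band and is
  clipped to that band; the phase is its running integral. Modeling the
  oscillation as a wandering sinusoid rather than as filtered noise is a
  deliberate design choice: it gives every sample an exact ground-truth
  phase (0 deg at the positive-going zero crossing, 90 deg at the positive
  peak), which is what makes exact phase-targeting tests possible.
  Amplitude is stage-dependent: 75 uV in N3, 40 in N2, 15 in N1, 10 in REM,
  5 in wake, reproducing the amplitude ordering the device's gating logic
  relies on.
* **Delta-band noise.** Band-limited (2--5 Hz) Gaussian noise with
  stage-scaled SD (30 uV in N3, 20 in N2, 8 in N1, 4 in REM, 3 in wake).
  This is what the device's 2--4 and 3--5 Hz classifier bands actually
  sense; without it a ~1 Hz slow oscillation alone would leave those bands
  empty.
* **1/f background.** Spectrally shaped Gaussian noise with exponent 1
  (configurable) and total SD 10 uV, flattened below 0.5 Hz so very-low
  frequency power stays bounded.
* **Wake activity.** Continuous 10 Hz alpha (12 uV) and 22 Hz beta (6 uV)
  during wake, so wake trips the classifier's beta ceiling as well as
  failing its delta minima.
* **Arousals and artifacts.** Arousals are 3--10 s additive alpha+beta
  bursts at 5/h of sleep; artifacts are 0.5--2 s half-sine excursions of
  400 uV peak at 2/h, deliberately exceeding the 300 uV amplitude veto.
  These are the minimal constructs that trip the stated vetoes and the
  offline artifact rejection.

Hypnograms use the five AASM stages on 20-s epochs, either as deterministic
bout lists or as a sticky first-order Markov chain whose stationary law can
be computed analytically (the tests use that as a brute-force oracle).

**Evoked response (the closed-loop hook).** Each delivered tone multiplies
the slow-oscillation amplitude over the next 4 slow-wave cycles by
`1 + g * v * r^(k-1)`, where `g` is the subject's response gain, `v` a
monotone volume weight (46--60 dB mapped linearly to 0.8--1.2), `r` in [0,1]
the saturation, and `k` the tone's index within its train (tones whose
effect windows chain). Effects of overlapping tones multiply, so marginal
gains shrink geometrically -- a minimal model of the refractoriness that
builds up under repeated stimulation, and the mechanism behind the
dose-dependent ON-OFF differences the analysis must recover. No quantitative
evoked-response magnitude is available to copy from real data, so `g` and
`r` are calibration knobs of the simulator, not empirical estimates: the
defaults (`g = 0.3`, `r = 0.7`; strong responders drawn from g in
[0.25, 0.35], weak from [0.05, 0.10]) were chosen once to give a clearly
detectable but saturating effect, and `g = 0` is exactly equivalent to sham.

## The device engine

The engine re-implements the real-time decision stack sample by sample, with
strictly causal processing (output at sample n depends only on samples up to
n; a truncation test verifies this):

1. **Preprocessing.** First-order RC high-pass at 0.1 Hz and a 50 Hz notch.
   The notch is realized as the standard RBJ biquad (Q = 30): a true
   spectral notch needs a conjugate zero pair, i.e. a second-order section,
   so this is the minimal faithful realization of a "simple" notch.
2. **Band powers.** Once per second, powers in the low-delta (2--4 Hz),
   high-delta (3--5 Hz) and high-beta (20--30 Hz) bands over the trailing
   4-s rectangular window, by direct spectral integration (sum of DFT bin
   contributions to variance). A separate 1-s high-beta power feeds the
   beta veto and the online arousal detector.
3. **Sleep gates.** NREM is declared when both delta powers exceed and beta
   stays below fixed thresholds. Stimulation is enabled only after 600 s of
   consecutive NREM (the first such span doubles as the night's
   no-stimulation control baseline); after any loss of NREM, re-enabling
   takes 180 s. A stricter delta threshold defines SWS (tones fire only in
   SWS), and beta power in the last second vetoes tones. The numeric
   thresholds are nowhere published, so they are calibrated once against the
   generator with a deterministic seed: delta minima at 25% of mean N2 band
   power, SWS minimum at 1.5x mean N2 low-delta (N3 passes, N2 does not),
   beta ceilings from the N3 beta distribution (95th percentile). They are
   plain config fields, not claims about the original device.
4. **Phase targeting.** A first-order phase-locked loop: phase detector
   `sign(x) * cos(theta)`, oscillator advancing at 1 Hz plus
   gain x error. A tone is triggered on the first sample in each PLL cycle
   where the estimated phase reaches 45 deg, subject to the reinforcement
   vetoes: positive preprocessed amplitude (no down-phase stimulation),
   amplitude at most 300 uV (artifact), and at least 0.5 s since the last
   event.
5. **Scheduling.** Continuous mode stimulates every eligible crossing;
   windowed mode alternates 6-s ON and OFF windows on a free-running 12-s
   clock anchored at the first enabled second of each stable-NREM period
   (ON first). OFF windows log marker triggers through the identical
   decision path; sham mode logs triggers everywhere and never touches the
   signal, which makes sham and verum runs event-identical when `g = 0`.
6. **Volume control.** Start at 52 dB; +1.5 dB after 7 consecutive quiet
   tones delivered at sufficient depth (capped at 60), -1.5 dB after
   arousals on 2 consecutive tones (floored at 46), reset to 52 whenever the
   minimum-delta condition fails. Three conditions the source material
   leaves open are fixed here and exposed in config: "sufficient depth" =
   SWS flag at tone time; "minimum delta" fails when low-delta power drops
   below half the SWS threshold; the online arousal criterion is 1-s beta
   power above the beta-veto threshold within 3 s after the tone.

**PLL gain.** The loop gain trades static error against ripple: a type-1
loop tracking a frequency offset df holds a static phase error that grows as
df/gain, while the phase-detector ripple grows with the gain. At the default
gain of 0.5 Hz per unit error the loop tracks a centered 1 Hz slow
oscillation with under 10 deg mean absolute error, and on full synthetic N3
nights ~94% of tones land in the 0--90 deg ground-truth up-phase with a
circular mean within a few degrees of the 45 deg target. Note one physical
consequence: after a frequency step to the edge of the slow-wave band
(e.g. 1.25 Hz), *no* first-order loop can return to <10 deg error -- the
static error at a 0.25 Hz offset is tens of degrees at any gain that still
has acceptable ripple. The tests therefore assert re-locking to the loop's
analytic static-error level, not to an unattainable absolute accuracy.

## The offline analysis

* **Filtering.** Zero-phase (forward-backward) Butterworth band-pass:
  3rd-order high-pass at 0.5 Hz and 4th-order low-pass at 40 Hz. Orders were
  chosen so the doubled-order filtfilt response stays within ~2% of unity at
  1 Hz while still rejecting DC and >40 Hz content.
* **Spectra.** Welch PSD of consecutive 6-s epochs: two 4-s Hamming
  segments at 50% overlap, 0.25 Hz bins, one-sided density scaling (a unit
  sinusoid integrates to 0.5 uV^2). lowSWA is the integrated bin power over
  bin centers in 0.75--1.25 Hz, endpoints inclusive -- the sum convention
  (power x bin width) is fixed here since mean-vs-sum is not defined by the
  source; it only rescales all lowSWA values by a constant. Normalized
  spectra (each bin divided by the cumulative bin power up to 30 Hz) are
  used only for spectral-ratio displays; all other analyses use absolute
  power.
* **Epoch selection.** A 6-s epoch enters analysis only when the device
  track and the hypnogram both label its entire span N2/N3, it contains no
  artifact (amplitude over 300 uV or flagged signal), and its peak amplitude
  passes a median +/- 3 scaled-MAD outlier rule computed over the night's
  dual-NREM epochs -- an explicit, automatic stand-in for the semiautomatic
  artifact screening used on real recordings.
* **ON-OFF contrast.** Scheduled 6-s windows meeting the same inclusion
  rules and containing at least one logged event are binned by their own
  event count (1--2, 3--4, >4; OFF windows by marker count); per-night
  per-bin mean lowSWA and ON - OFF differences are reported, plus the
  >2-stimulation aggregate that the responder criterion uses.
* **lowSWE.** Per-night lowSWA summed over all included NREM epochs.
* **Evoked responses.** Event-locked averages of the filtered signal over
  [-1, +3] s with baseline correction by the mean of the 0.5 s pre-event
  (window and baseline are package defaults, exposed as arguments).
* **Arousals (offline).** Alpha (8--12 Hz) and beta (16--40 Hz) short-time
  power in 1-s windows stepped by 0.5 s, thresholded at the median + 6
  scaled MADs of the surrounding 5 minutes per band, events of at least 3 s,
  merged when closer than 3 s, wake excluded. The MAD multiplier was set so
  clean synthetic NREM yields no false detections while planted bursts are
  found; this simplified band-power detector deliberately replaces the
  published external algorithm, which is out of scope.
* **Night QC.** A night is excluded when more than 20 min of signal are
  flagged bad or the recording is partial.
* **Sleep latency** is the time from recording start to the first epoch of
  any sleep stage (the convention is not externally defined; this one is
  fixed and documented here).

## Statistics

* `classify_responders()`: median split on per-subject mean Verum ON-OFF
  lowSWA difference over >2-stimulation windows; upper half = strong. For
  odd n the upper ceiling(n/2) are strong; exact ties resolve by subject id
  and are flagged. The split is invariant to monotone rescaling of the
  criterion.
* `rm_correlation()`: repeated-measures correlation as the shared-slope,
  subject-specific-intercept ANCOVA; `r_rm = sign(slope) *
  sqrt(SS_x / (SS_x + SS_err))`, df = N - k - 1, CI via Fisher z with
  SE = 1/sqrt(df - 1). Verified against a brute-force within-subject
  centering oracle to 1e-10.
* `lda_crossval()`: Fisher LDA (via MASS) in stratified 10-fold CV with a
  fixed seed (stratification is a package choice; it also guarantees no
  single-class training fold whenever each class has two members), pooled
  held-out accuracy/sensitivity/specificity, and a one-tailed binomial test
  against the No Information Rate.
* `two_group_t()` and `chi2_2x2()`: pooled-variance Student t (working from
  raw data or published mean/SEM/n summaries) and Pearson chi-square without
  continuity correction -- the demographics worked examples.
* Mixed-effects and cumulative-link models are deliberately not
  re-implemented; `cohort_long_table()` exports the tidy per-night per-bin
  table those models would consume.

## Problem sizes and determinism

Simulated-trial checks run at desk scale by design: 60--100 min nights
(deterministic bout templates with two to three N3 periods), cohorts of 8
subjects (4 strong / 4 weak) with 3 nights per condition in the windowed
approach, and a 10-seed replication of responder-label recovery on a reduced
one-night design. Every generator and analysis output is a pure function of
(template, parameters, seed); cohort designs carry per-night derived seeds so
any single night can be regenerated bit-for-bit.

## What the synthetic tests do and do not show

Passing tests demonstrate that the decision stack implements its stated
rules exactly (refractory, windows, volume walk, gating times), that the
phase targeting meets its documented accuracy against ground truth, and that
the analysis pipeline recovers planted dose-response structure and planted
responder traits, with exact nulls under sham. They do not validate the
biology: the generator has no spindles, K-complexes, ECG contamination or
realistic topography, its evoked response is a stylized multiplicative
envelope, and the gate thresholds are calibrated to this generator rather
than to any physical device. Results on real recordings would additionally
depend on scorer quality, electrode artifacts and inter-subject spectral
variability that this model intentionally omits.
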