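# somnoloop

Desk-scale simulator and analysis toolkit for **closed-loop auditory
slow-wave stimulation** of sleep EEG.

Auditory stimulation devices for deep sleep listen to one frontal EEG
channel in real time, decide when the sleeper is in stable NREM sleep,
track the instantaneous phase of the ~1 Hz slow oscillation with a
phase-locked loop, and play 50-ms pink-noise bursts timed to the wave's
depolarized *up-phase* (0–90°, target 45°), with the goal of enhancing
slow-wave activity. Evaluating such a system — and the offline analysis
that quantifies its effect — requires nights of polysomnography with known
ground truth, which real trials cannot provide. somnoloop therefore couples:

* **`synthgen`** — a synthetic polysomnography generator: stage-dependent
  slow oscillation with exact per-sample phase, 1/f background, delta-band
  noise, wake alpha/beta, arousals, artifacts, and a saturating
  dose-dependent evoked response to tones
  (`1 + g·v·r^(k−1)` amplitude scaling over the next cycles per tone);
* **`engine`** — the device's real-time decision stack: causal 0.1 Hz
  high-pass + 50 Hz notch, per-second band powers (low delta 2–4 Hz, high
  delta 3–5 Hz, high beta 20–30 Hz), the 10-min/3-min stable-NREM gate,
  SWS and beta vetoes, a first-order PLL with per-cycle 45° trigger
  latching, 0.5 s refractory, 300 µV artifact ceiling, adaptive
  46–60 dB volume control in 1.5 dB steps, and continuous vs 6-s
  ON/OFF windowed scheduling (sham mode logs silent triggers through the
  identical stack);
* **`analysis`** — the offline pipeline: zero-phase 0.5–40 Hz filtering,
  Welch spectra of 6-s epochs (4-s Hamming segments, 50% overlap),
  normalization by cumulative power to 30 Hz, lowSWA (0.75–1.25 Hz),
  dual (device + hypnogram) NREM epoch selection with MAD outlier
  rejection, ON–OFF window contrasts binned by stimulation count
  (1–2 / 3–4 / >4), lowSWE, evoked responses, arousal detection, night QC;
* **`stats`** — responder classification (median split on the Verum
  ON−OFF lowSWA difference in >2-stimulation windows), repeated-measures
  correlation, 10-fold cross-validated LDA with a No-Information-Rate
  binomial test, pooled t and Pearson χ² worked examples.

## Worked example

Simulate a 58-minute night with two N3-rich periods, run the closed-loop
engine in the windowed verum mode, and summarize the stimulation effect:

```r
library(somnoloop)
hyp    <- generate_hypnogram(stage_bouts(c("W", "N2", "N3"), c(3, 10, 45)))
params <- gen_params()            # response gain g = 0.3, saturation r = 0.7
night  <- generate_night(hyp, params, seed = 42)
cfg    <- engine_config(params, mode = "verum", approach = "windowed")
run    <- run_night(night, cfg)
run
#> <stim_run> verum/windowed: 845 events (423 tones), volume 46.0-53.5 dB
#>   baseline window 687-1287 s

summ <- summarize_night(run, night, cfg)
summ
#> <night_summary> baseline lowSWA 2420.9 uV^2; lowSWE 1566419; 842 NREM stims; mean vol 48.9 dB
#>   ON-OFF lowSWA diff (>2 stim): 3328.25 uV^2
summ$onoff$bins
#>   bin mean_on mean_off   diff n_on n_off
#> 1 1-2    3820     2972  847.3    7     5
#> 2 3-4    5704     3156 2548.3   11    19
#> 3  >4    6806     3132 3673.2   25    34
```

Reading the output: the device found stable NREM and banked its 10-minute
no-stimulation baseline at 687–1287 s; 423 tones were delivered inside 6-s ON
windows (the 422 other events are OFF-window markers). ON windows carry more
0.75–1.25 Hz power than their OFF neighbours, and the difference grows with
the number of stimulations per window — the planted dose-dependent response,
recovered by the analysis. Against the generator's ground-truth phase, 97%
of tones landed in the 0–90° up-phase with a circular mean of 45.2°.

With `response_gain = 0` (or `mode = "sham"`) the same pipeline returns
ON−OFF differences statistically indistinguishable from zero, and sham and
verum runs produce event-identical logs.

A thin CLI wraps the same functions
(`inst/cli/somnoloop simulate-night | run-engine | full-pipeline`).

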