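#' Causal real-time preprocessing
#'
#' The device's front end: a first-order RC high-pass at `hp_cutoff` Hz (DC
#' rejection) followed by a biquad notch at `notch_freq` Hz (power-line
#' rejection). Strictly causal: the output at sample n depends only on
#' samples up to n. Non-finite input samples are flagged in the QC mask and
#' replaced by zero before filtering.
#'
#' @param x raw EEG samples, uV.
#' @param config an [engine_config()] (or any list with `fs`, `notch_freq`,
#'   `notch_q`, `hp_cutoff`).
#' @return list with `samples` (filtered stream) and `qc` (logical per-sample
#'   non-finite flags).
#' @export
preprocess_stream <- function(x, config = engine_config(NULL)) {
  cpp_preprocess(as.numeric(x), config$fs, config$notch_freq,
                 config$notch_q, config$hp_cutoff)
}

#' Filter coefficients of the causal preprocessing chain
#'
#' Returns the difference-equation coefficients of the high-pass and notch
#' stages so their frequency response can be evaluated analytically
#' (`H(z) = B(z)/A(z)` at `z = exp(2i*pi*f/fs)`), e.g. as an independent
#' oracle for the filter's attenuation.
#'
#' @param config an [engine_config()].
#' @return list with elements `hp` and `notch`, each `list(b, a)`.
#' @export
preproc_coefs <- function(config = engine_config(NULL)) {
  fs <- config$fs
  rc <- 1 / (2 * pi * config$hp_cutoff)
  a_hp <- rc / (rc + 1 / fs)
  w0 <- 2 * pi * config$notch_freq / fs
  alpha <- sin(w0) / (2 * config$notch_q)
  a0 <- 1 + alpha
  list(hp = list(b = c(a_hp, -a_hp), a = c(1, -a_hp)),
       notch = list(b = c(1, -2 * cos(w0), 1) / a0,
                    a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0)))
}

#' Sliding band-power estimate
#'
#' The engine's spectral feature extractor: once per second, the power (uV^2,
#' contribution to signal variance) in each configured band is computed by
#' direct spectral integration over the trailing `window_sec` rectangular
#' window. Rows before the buffer has filled are `NA`.
#'
#' @param x (filtered) samples.
#' @param config an [engine_config()]; bands taken from its
#'   `low_delta_band`, `high_delta_band`, `high_beta_band`.
#' @param bands optional matrix (rows = bands, columns lo, hi Hz) overriding
#'   the configured bands.
#' @param window_sec analysis window length, seconds.
#' @return matrix, one row per second, one column per band.
#' @export
band_power_track <- function(x, config = engine_config(NULL), bands = NULL,
                             window_sec = config$bp_window) {
  if (is.null(bands))
    bands <- rbind(low_delta = config$low_delta_band,
                   high_delta = config$high_delta_band,
                   high_beta = config$high_beta_band)
  out <- cpp_band_power_track(as.numeric(x), config$fs, window_sec,
                              as.matrix(bands))
  colnames(out) <- rownames(bands)
  out
}

#' One-step / whole-stream first-order PLL phase tracking
#'
#' A first-order phase-locked loop estimating the instantaneous EEG phase at
#' every sample with no look-ahead. Phase detector: `sign(x) * cos(theta)`;
#' the oscillator advances at `center_freq + gain * error` Hz. With zero
#' input the loop free-runs at exactly `center_freq`. Phase convention
#' matches the generator: 0 deg at the positive-going zero crossing, 90 deg
#' at the positive peak.
#'
#' @param x filtered EEG samples.
#' @param config an [engine_config()] (uses `fs`, `pll_center_freq`,
#'   `pll_gain`).
#' @param init_phase_deg initial oscillator phase, degrees.
#' @return numeric vector of phase estimates in degrees `[0, 360)`.
#' @export
pll_track <- function(x, config = engine_config(NULL), init_phase_deg = 0) {
  cpp_pll_track(as.numeric(x), config$fs, config$pll_center_freq,
                config$pll_gain, init_phase_deg * pi / 180)
}

#' @rdname pll_track
#' @param state list with `phase_deg` (current estimate); created on first
#'   call with `pll_state()`.
#' @param sample one input sample.
#' @return `pll_step`: the updated state.
#' @export
pll_step <- function(state, sample, config = engine_config(NULL)) {
  theta <- state$phase_deg * pi / 180
  e <- sign(sample) * cos(theta)
  theta <- theta + 2 * pi * (config$pll_center_freq + config$pll_gain * e) / config$fs
  state$phase_deg <- (theta * 180 / pi) %% 360
  state
}

#' @rdname pll_track
#' @export
pll_state <- function(init_phase_deg = 0) list(phase_deg = init_phase_deg)

#' Sleep-gate state update (one 1-s step)
#'
#' Pure-functional form of the engine's gating logic, updated once per
#' second: NREM flag from the three band-power thresholds; a stable-NREM
#' counter that accumulates while the flag holds and resets on loss;
#' stimulation enabled after 600 s of the first stable period (which doubles
#' as the night's no-stimulation baseline) or 180 s of later periods; SWS
#' flag from the SWS delta threshold; beta veto from the last-second beta
#' power.
#'
#' @param gates state list from [gate_state()].
#' @param bands named list/vector with `low_delta`, `high_delta`,
#'   `high_beta` (4-s powers) and `beta_1s` (last-second beta power), uV^2.
#' @param config an [engine_config()].
#' @param t_s current time, seconds (used to record the baseline window).
#' @return updated gate state.
#' @export
update_sleep_gates <- function(gates, bands, config, t_s = NA_real_) {
  nrem <- bands[["low_delta"]] >= config$low_delta_min &&
    bands[["high_delta"]] >= config$high_delta_min &&
    bands[["high_beta"]] <= config$nrem_beta_max
  if (nrem) {
    gates$stable_nrem_elapsed <- gates$stable_nrem_elapsed + 1
  } else {
    gates$stable_nrem_elapsed <- 0
    gates$stim_enabled <- FALSE
  }
  gates$nrem_flag <- nrem
  need <- if (gates$first_period_done) config$stable_nrem_followup
          else config$stable_nrem_initial
  if (!gates$stim_enabled && gates$stable_nrem_elapsed >= need) {
    gates$stim_enabled <- TRUE
    if (!gates$first_period_done) {
      gates$first_period_done <- TRUE
      if (!is.na(t_s))
        gates$baseline_window <- c(t_s - config$stable_nrem_initial, t_s)
    }
  }
  gates$sws_flag <- bands[["low_delta"]] >= config$sws_delta_min
  gates$beta_veto <- bands[["beta_1s"]] > config$beta_veto_max
  gates
}

#' @rdname update_sleep_gates
#' @export
gate_state <- function() {
  list(nrem_flag = FALSE, stable_nrem_elapsed = 0, stim_enabled = FALSE,
       sws_flag = FALSE, beta_veto = FALSE, baseline_window = NULL,
       first_period_done = FALSE)
}

#' Single stimulation decision
#'
#' The reinforcement logic applied at a target-phase crossing: emit an event
#' iff stimulation is enabled, the SWS flag holds, no beta veto, the
#' preprocessed amplitude is positive (up-phase, not down-phase) and at most
#' the 300 uV artifact ceiling, at least the 0.5 s refractory has elapsed
#' since the previous event, and (in the windowed approach) the scheduler is
#' in a window. ON windows (and the continuous approach) produce a tone in
#' verum mode and a silent trigger in sham; OFF windows always produce a
#' marker trigger.
#'
#' @param gates gate state (see [gate_state()]).
#' @param amplitude current preprocessed EEG amplitude, uV.
#' @param t_s current time, s.
#' @param last_event_t time of the previous event, s (`-Inf` if none).
#' @param config an [engine_config()].
#' @param window_label `"ON"`, `"OFF"` or `"NA"` (continuous).
#' @return `NULL` (vetoed; with attribute `veto` naming the first failing
#'   condition) or a list `(t_s, kind, window_label)`.
#' @export
decide_trigger <- function(gates, amplitude, t_s, last_event_t, config,
                           window_label = "NA") {
  veto <- function(reason) structure(list(), veto = reason, class = "veto")
  if (!gates$stim_enabled || !gates$sws_flag) return(veto("gate"))
  if (gates$beta_veto) return(veto("beta"))
  if (amplitude <= 0) return(veto("negative_amplitude"))
  if (abs(amplitude) > config$amplitude_ceiling) return(veto("amplitude_ceiling"))
  if (t_s - last_event_t < config$refractory) return(veto("refractory"))
  stim_slot <- window_label != "OFF"
  kind <- if (config$mode == "verum" && stim_slot) "tone" else "trigger"
  list(t_s = t_s, kind = kind, window_label = window_label)
}

#' Volume-controller state update
#'
#' Called after each tone's 3-s post-stimulus window has been evaluated:
#' after `tones_before_increase` consecutive quiet tones delivered at
#' sufficient sleep depth the volume rises one `volume_step` (capped at
#' `volume_max`); after `arousals_before_decrease` consecutive tones with a
#' detected arousal it falls one step (floored at `volume_min`); whenever the
#' minimum-delta condition fails the volume resets to `volume_default` and
#' both counters clear.
#'
#' @param vol state list from [volume_state()].
#' @param arousal was an arousal detected after this tone?
#' @param depth_ok was the SWS depth condition met at tone time?
#' @param min_delta_ok does the minimum-delta condition currently hold?
#' @param config an [engine_config()].
#' @return updated volume state.
#' @export
update_volume <- function(vol, arousal, depth_ok = TRUE, min_delta_ok = TRUE,
                          config = engine_config(NULL)) {
  if (!min_delta_ok) {
    return(list(volume = config$volume_default,
                consecutive_quiet_tones = 0, consecutive_arousal_tones = 0))
  }
  if (arousal) {
    vol$consecutive_quiet_tones <- 0
    vol$consecutive_arousal_tones <- vol$consecutive_arousal_tones + 1
    if (vol$consecutive_arousal_tones >= config$arousals_before_decrease) {
      vol$volume <- max(config$volume_min, vol$volume - config$volume_step)
      vol$consecutive_arousal_tones <- 0
    }
  } else {
    vol$consecutive_arousal_tones <- 0
    if (depth_ok) {
      vol$consecutive_quiet_tones <- vol$consecutive_quiet_tones + 1
      if (vol$consecutive_quiet_tones >= config$tones_before_increase) {
        vol$volume <- min(config$volume_max, vol$volume + config$volume_step)
        vol$consecutive_quiet_tones <- 0
      }
    }
  }
  vol
}

#' @rdname update_volume
#' @export
volume_state <- function(config = engine_config(NULL)) {
  list(volume = config$volume_default,
       consecutive_quiet_tones = 0, consecutive_arousal_tones = 0)
}

#' Run the closed-loop engine over a synthetic night
#'
#' Orchestrates the whole real-time stack sample-by-sample over a
#' [generate_night()] source: causal preprocessing, per-second band powers
#' and sleep gates, PLL phase tracking with per-cycle target-phase latching,
#' reinforcement vetoes, ON/OFF window scheduling, and the adaptive volume
#' controller. In verum mode each delivered tone notifies the generator,
#' which enhances the slow oscillation over the following cycles (closing
#' the loop); in sham mode the identical decision stack runs but only silent
#' triggers are logged and the signal is untouched.
#'
#' @param night a `psg_night`.
#' @param config an [engine_config()].
#' @return object of class `stim_run`: list with `log` (data.frame `t_s`,
#'   `kind`, `volume_db`, `phase_est_deg`, `window_label`, `window_index`),
#'   `track` (per-second data.frame `second`, `nrem`, `sws`, `beta_veto`,
#'   `stim_enabled`, `window`), `baseline_window` (`c(start, end)` seconds of
#'   the first 600-s stable-NREM span, or `NULL`), `qc_sec` (per-second bad
#'   signal flags), `eeg` (the realized signal including any evoked
#'   enhancement), `vetoes` (crossing veto counters), `config`.
#' @export
run_night <- function(night, config = engine_config(night$params)) {
  stopifnot(inherits(night, "psg_night"))
  validate_engine_config(config)
  if (night$fs != config$fs)
    stop(sprintf("sampling-rate mismatch: night %g Hz vs config %g Hz",
                 night$fs, config$fs))
  cc <- unclass(config)
  cc$verum <- config$mode == "verum"
  cc$windowed <- config$approach == "windowed"
  res <- cpp_run_night(night$phase, night$sw_amp, night$bg, night$fs, cc,
                       night$params$response_gain,
                       night$params$response_saturation,
                       night$params$response_duration)
  log <- data.frame(t_s = res$t_s, kind = res$kind,
                    volume_db = res$volume_db,
                    phase_est_deg = res$phase_est_deg,
                    window_label = res$window_label,
                    window_index = ifelse(res$window_index < 0, NA_integer_,
                                          res$window_index),
                    stringsAsFactors = FALSE)
  baseline <- if (is.na(res$baseline_start)) NULL else
    c(start = res$baseline_start, end = res$baseline_end)
  structure(list(log = log, track = res$track, baseline_window = baseline,
                 qc_sec = res$qc_sec, eeg = res$eeg, vetoes = res$vetoes,
                 config = config),
            class = "stim_run")
}

#' @export
print.stim_run <- function(x, ...) {
  cat(sprintf("<stim_run> %s/%s: %d events (%d tones), volume %.1f-%.1f dB\n",
              x$config$mode, x$config$approach, nrow(x$log),
              sum(x$log$kind == "tone"),
              if (nrow(x$log)) min(x$log$volume_db) else NA,
              if (nrow(x$log)) max(x$log$volume_db) else NA))
  if (!is.null(x$baseline_window))
    cat(sprintf("  baseline window %.0f-%.0f s\n",
                x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}
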