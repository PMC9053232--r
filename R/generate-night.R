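#' Generate one night of synthetic polysomnography
#'
#' Builds a single-channel EEG (uV, sampled at `params$fs`) from a hypnogram:
#' a slow oscillation with stage-dependent amplitude and a ground-truth
#' per-sample phase, stage-scaled delta-band noise, a 1/f background, wake
#' alpha/beta activity, stochastic arousal bursts and high-amplitude
#' artifacts. The slow oscillation is a frequency-wandering sinusoid (an
#' Ornstein-Uhlenbeck-perturbed instantaneous frequency clipped to
#' `sw_freq_band`) so an exact per-sample phase exists: phase 0 deg is the
#' positive-going zero crossing and 90 deg the positive peak, so the slow-wave
#' "up-phase" is the 0--90 deg range.
#'
#' @param hyp a [hypnogram()].
#' @param params a [gen_params()].
#' @param seed integer seed; the night is a pure function of
#'   `(hyp, params, seed)`.
#' @return An object of class `psg_night` with elements `eeg` (uV), `fs`,
#'   `hypnogram`, `stage` (per-sample stage code into `W,N1,N2,N3,R`),
#'   `phase` (unwrapped slow-oscillation phase, radians), `sw_amp`
#'   (per-sample slow-oscillation amplitude, uV), `bg` (everything except the
#'   slow oscillation, uV), `events` (arousal/artifact intervals), `params`,
#'   `seed`. `ground_truth_phase_deg()` returns the wrapped phase in degrees.
#' @export
generate_night <- function(hyp, params = gen_params(), seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  validate_gen_params(params)
  fs <- params$fs
  stage <- stage_track(hyp, fs)
  n <- length(stage)
  with_seed(seed, {
    # --- slow oscillation: OU-wandering instantaneous frequency -> phase
    f0 <- mean(params$sw_freq_band)
    dt <- 1 / fs
    phi_ar <- exp(-dt / params$sw_freq_tau)
    innov_sd <- params$sw_freq_sigma * sqrt(1 - phi_ar^2)
    freq <- f0 + as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi_ar,
                                          method = "recursive"))
    freq <- pmin(pmax(freq, params$sw_freq_band[1]), params$sw_freq_band[2])
    phase <- runif(1, 0, 2 * pi) + cumsum(2 * pi * freq / fs)
    sw_amp <- params$stage_sw_amplitude[stage]

    # --- backgrounds
    bg <- pink_noise(n, fs, params$background_1f_exponent,
                     params$background_1f_scale)
    delta_sd <- params$stage_delta_amplitude[stage]
    bg <- bg + band_noise(n, fs, c(2, 5)) * delta_sd
    t <- (seq_len(n) - 1) / fs
    wake <- stage == 1L
    if (any(wake) && (params$wake_alpha_amp > 0 || params$wake_beta_amp > 0)) {
      bg[wake] <- bg[wake] +
        params$wake_alpha_amp * sin(2 * pi * 10 * t[wake]) +
        params$wake_beta_amp * sin(2 * pi * 22 * t[wake])
    }

    # --- arousal bursts (3-10 s alpha+beta, during sleep) and artifacts
    events <- data.frame(type = character(0), onset_s = numeric(0),
                         duration_s = numeric(0))
    sleep_idx <- which(stage != 1L)
    hours <- n / fs / 3600
    n_arousal <- rpois(1, params$arousal_rate * hours)
    if (n_arousal > 0 && length(sleep_idx) > fs) {
      for (k in seq_len(n_arousal)) {
        dur <- runif(1, 3, 10)
        s0 <- sample(sleep_idx, 1)
        idx <- s0:min(n, s0 + round(dur * fs) - 1)
        env <- sin(pi * seq_along(idx) / length(idx))^2
        bg[idx] <- bg[idx] + env *
          (params$arousal_alpha_amp * sin(2 * pi * 10 * t[idx]) +
           params$arousal_beta_amp * sin(2 * pi * 23 * t[idx]))
        events <- rbind(events, data.frame(type = "arousal",
                                           onset_s = (s0 - 1) / fs,
                                           duration_s = length(idx) / fs))
      }
    }
    n_artifact <- rpois(1, params$artifact_rate * hours)
    if (n_artifact > 0) {
      for (k in seq_len(n_artifact)) {
        dur <- runif(1, 0.5, 2)
        s0 <- sample.int(n - round(2 * fs), 1)
        idx <- s0:(s0 + round(dur * fs) - 1)
        bg[idx] <- bg[idx] +
          params$artifact_amp * sin(pi * seq_along(idx) / length(idx))
        events <- rbind(events, data.frame(type = "artifact",
                                           onset_s = (s0 - 1) / fs,
                                           duration_s = length(idx) / fs))
      }
    }
    events <- events[order(events$onset_s), ]
    rownames(events) <- NULL

    bg <- unname(bg)
    structure(list(eeg = unname(sw_amp * sin(phase)) + bg,
                   fs = fs, hypnogram = hyp, stage = stage,
                   phase = phase, sw_amp = unname(sw_amp), bg = bg,
                   events = events, params = params, seed = seed),
              class = "psg_night")
  })
}

#' @export
print.psg_night <- function(x, ...) {
  cat(sprintf("<psg_night> %.1f min at %g Hz (%d samples), %d events\n",
              length(x$eeg) / x$fs / 60, x$fs, length(x$eeg), nrow(x$events)))
  print(x$hypnogram)
  invisible(x)
}

#' Ground-truth slow-oscillation phase in degrees
#' @param night a `psg_night`.
#' @return numeric vector in `[0, 360)`, one value per sample; 0 deg at the
#'   positive-going zero crossing, 90 deg at the positive peak.
#' @export
ground_truth_phase_deg <- function(night) {
  (night$phase * 180 / pi) %% 360
}

# 1/f^alpha noise via frequency-domain shaping, scaled to SD `scale`.
pink_noise <- function(n, fs, alpha = 1, scale = 1) {
  if (scale <= 0) return(numeric(n))
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  f0 <- 0.5  # flatten below 0.5 Hz so DC/very-low-f power stays bounded
  g <- ifelse(f < f0, f0, f)^(-alpha / 2)
  g[1] <- 0
  y <- Re(fft(X * g, inverse = TRUE)) / n
  scale * y / sd(y)
}

# unit-SD band-limited Gaussian noise (2nd-order Butterworth band-pass)
band_noise <- function(n, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filter(bf, rnorm(n))
  y <- as.numeric(y)
  s <- sd(y)
  if (s == 0) y else y / s
}

#' Apply tone-evoked slow-wave enhancement to a night
#'
#' Implements the generator's dose-dependent, saturating response model:
#' a tone at time `t` with volume `v_db` multiplies the slow-oscillation
#' amplitude over the next `response_duration` slow-wave cycles by
#' `1 + g * v * r^(k-1)`, where `v = volume_weight(v_db)` and `k` is the
#' tone's index within its train (a train chains tones whose effect windows
#' overlap). Overlapping effects multiply, so the marginal multiplier per
#' tone is non-increasing in `k`.
#'
#' This is the offline/batch form of the stimulus notification used inside
#' the closed loop; [run_night()] applies the identical rule sample-by-sample.
#'
#' @param night a `psg_night`.
#' @param times tone onset times, seconds (non-decreasing).
#' @param volumes tone volumes, dB (recycled).
#' @param params response parameters; defaults to the night's own.
#' @return list with `multiplier` (per-sample envelope multiplier) and `eeg`
#'   (the night's EEG with the enhanced slow oscillation).
#' @export
apply_stim_effects <- function(night, times, volumes = 52,
                               params = night$params) {
  stopifnot(inherits(night, "psg_night"))
  n <- length(night$eeg)
  m <- rep(1, n)
  if (length(times) == 0L)
    return(list(multiplier = m, eeg = night$eeg))
  if (is.unsorted(times)) stop("stimulus times must be non-decreasing")
  if (any(times < 0) || any(times > n / night$fs))
    stop("stimulus time outside the recording")
  volumes <- rep_len(volumes, length(times))
  g <- params$response_gain
  r <- params$response_saturation
  dphi <- params$response_duration * 2 * pi
  k <- 0L
  train_end <- -1L
  for (i in seq_along(times)) {
    s <- min(n, floor(times[i] * night$fs) + 1L)
    k <- if (s <= train_end) k + 1L else 1L
    # effect lasts until the slow oscillation advances response_duration cycles
    e <- s + findInterval(night$phase[s] + dphi, night$phase[s:n])
    e <- min(e, n)
    fac <- 1 + g * volume_weight(volumes[i]) * r^(k - 1L)
    m[s:e] <- m[s:e] * fac
    train_end <- max(train_end, e)
  }
  list(multiplier = m, eeg = (m * night$sw_amp) * sin(night$phase) + night$bg)
}
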