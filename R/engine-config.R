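#' Device engine configuration
#'
#' Collects every tunable of the real-time stimulation stack. Values with a
#' printed source default to it: 250 Hz sampling, 50 Hz notch, 0.1 Hz
#' high-pass, classifier bands low delta 2--4 Hz / high delta 3--5 Hz / high
#' beta 20--30 Hz, 10 min initial and 3 min follow-up stable-NREM gates,
#' 45 deg target phase, 0.5 s refractory, 300 uV amplitude ceiling,
#' 52/46/60 dB default/min/max volume with 1.5 dB steps, 7 quiet tones before
#' an increase, 2 consecutive arousals before a decrease, 6 s ON/OFF windows.
#'
#' The band-power thresholds of the NREM/SWS/beta gates are not published;
#' they are calibrated once against the synthetic generator (see
#' [calibrate_thresholds()]) and exposed here so every run is reproducible.
#' The PLL loop gain is likewise a calibrated repo default: see the methods
#' vignette.
#'
#' @param gen_params [gen_params()] used to calibrate the gate thresholds; if
#'   `NULL`, the thresholds must be supplied explicitly via `...`.
#' @param mode `"verum"` (audible tones) or `"sham"` (silent triggers,
#'   identical decision stack).
#' @param approach `"windowed"` (alternating 6 s ON/OFF) or `"continuous"`.
#' @param ... overrides for any config field.
#' @return list of class `engine_config`.
#' @export
engine_config <- function(gen_params = gen_params(),
                          mode = c("verum", "sham"),
                          approach = c("windowed", "continuous"), ...) {
  mode <- match.arg(mode)
  approach <- match.arg(approach)
  cfg <- list(
    fs = 250,
    notch_freq = 50, notch_q = 30, hp_cutoff = 0.1,
    low_delta_band = c(2, 4), high_delta_band = c(3, 5),
    high_beta_band = c(20, 30),
    low_delta_min = NA_real_, high_delta_min = NA_real_,
    nrem_beta_max = NA_real_, sws_delta_min = NA_real_,
    beta_veto_max = NA_real_,
    stable_nrem_initial = 600, stable_nrem_followup = 180,
    target_phase = 45, refractory = 0.5, amplitude_ceiling = 300,
    volume_default = 52, volume_min = 46, volume_max = 60,
    volume_step = 1.5, tones_before_increase = 7,
    arousals_before_decrease = 2,
    mode = mode, approach = approach, window_len = 6,
    pll_center_freq = 1, pll_gain = 0.5,
    bp_window = 4, arousal_eval_window = 3)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.null(gen_params) && anyNA(c(cfg$low_delta_min, cfg$high_delta_min,
                                      cfg$nrem_beta_max, cfg$sws_delta_min,
                                      cfg$beta_veto_max))) {
    thr <- calibrate_thresholds(gen_params, cfg)
    for (f in names(thr)) if (is.na(cfg[[f]])) cfg[[f]] <- thr[[f]]
  }
  validate_engine_config(cfg)
  class(cfg) <- "engine_config"
  cfg
}

validate_engine_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$refractory > 0, cfg$window_len > 0,
            cfg$volume_min <= cfg$volume_default,
            cfg$volume_default <= cfg$volume_max,
            cfg$stable_nrem_initial > 0, cfg$stable_nrem_followup > 0,
            cfg$mode %in% c("verum", "sham"),
            cfg$approach %in% c("windowed", "continuous"))
  for (b in list(cfg$low_delta_band, cfg$high_delta_band, cfg$high_beta_band))
    stopifnot(length(b) == 2L, b[1] < b[2], b[1] > 0)
  invisible(cfg)
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("<engine_config> %s / %s\n", x$mode, x$approach))
  cat(sprintf("  gates: low-delta>=%.3g high-delta>=%.3g beta<=%.3g uV^2; SWS delta>=%.3g; beta veto>%.3g\n",
              x$low_delta_min, x$high_delta_min, x$nrem_beta_max,
              x$sws_delta_min, x$beta_veto_max))
  cat(sprintf("  PLL %g Hz center, gain %g; target %g deg; refractory %g s\n",
              x$pll_center_freq, x$pll_gain, x$target_phase, x$refractory))
  invisible(x)
}

# threshold cache keyed by the serialized generator parameters
.threshold_cache <- new.env(parent = emptyenv())

#' Calibrate the engine's band-power gate thresholds
#'
#' Generates short artifact-free pure-N2 and pure-N3 segments from the
#' synthetic model and measures their band powers with the engine's own
#' estimator (trailing 4-s rectangular window, once per second). Thresholds:
#' low/high-delta NREM minima at 25% of mean N2 band power; NREM beta ceiling
#' at twice the 95th percentile of N3 high-beta; SWS delta minimum at 1.5x
#' mean N2 low-delta (passed by N3, not by N2); beta veto at the 95th
#' percentile of N3 1-s high-beta power. A fixed internal seed makes the
#' calibration deterministic.
#'
#' @param params a [gen_params()].
#' @param cfg partial engine config (bands and estimator settings).
#' @return named list of the five thresholds (uV^2).
#' @export
calibrate_thresholds <- function(params, cfg = NULL) {
  if (is.null(cfg))
    cfg <- list(fs = params$fs, notch_freq = 50, notch_q = 30,
                hp_cutoff = 0.1, low_delta_band = c(2, 4),
                high_delta_band = c(3, 5), high_beta_band = c(20, 30),
                bp_window = 4)
  key <- paste(c(deparse(params[names(params) != "response_gain"]),
                 deparse(cfg$low_delta_band), deparse(cfg$high_delta_band),
                 deparse(cfg$high_beta_band)), collapse = ";")
  hit <- get0(key, envir = .threshold_cache)
  if (!is.null(hit)) return(hit)
  calib_params <- params
  calib_params$arousal_rate <- 0
  calib_params$artifact_rate <- 0
  seg <- function(stage) {
    night <- generate_night(generate_hypnogram(stage_bouts(stage, 2)),
                            calib_params, seed = 761L)
    pp <- preprocess_stream(night$eeg, cfg)
    bands <- rbind(cfg$low_delta_band, cfg$high_delta_band,
                   cfg$high_beta_band)
    p4 <- cpp_band_power_track(pp$samples, params$fs, cfg$bp_window, bands)
    p1 <- cpp_band_power_track(pp$samples, params$fs, 1, rbind(cfg$high_beta_band))
    keep <- stats::complete.cases(p4)
    keep[seq_len(min(10, length(keep)))] <- FALSE  # drop filter transient
    list(p4 = p4[keep, , drop = FALSE], p1 = p1[keep, , drop = FALSE])
  }
  n2 <- seg("N2"); n3 <- seg("N3")
  thr <- list(
    low_delta_min = 0.25 * mean(n2$p4[, 1]),
    high_delta_min = 0.25 * mean(n2$p4[, 2]),
    nrem_beta_max = 2 * stats::quantile(n3$p4[, 3], 0.95, names = FALSE),
    sws_delta_min = 1.5 * mean(n2$p4[, 1]),
    beta_veto_max = stats::quantile(n3$p1[, 1], 0.95, names = FALSE))
  assign(key, thr, envir = .threshold_cache)
  thr
}
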