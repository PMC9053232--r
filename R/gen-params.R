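#' Synthetic polysomnography generator parameters
#'
#' Parameters of the single-channel EEG model: a frequency-wandering slow
#' oscillation whose amplitude depends on sleep stage, a 1/f background,
#' stage-scaled delta-band noise, wake alpha/beta activity, arousal bursts,
#' high-amplitude artifacts, and a saturating dose-dependent evoked response
#' to delivered tones.
#'
#' The evoked-response model is the closed-loop hook: each effective tone
#' multiplies the slow-oscillation amplitude over the next
#' `response_duration` slow-wave cycles by `1 + g * v * r^(k-1)` where `g` is
#' `response_gain`, `v` the monotone volume weight (46--60 dB mapped linearly
#' to 0.8--1.2), `r` the `response_saturation` in `[0,1]`, and `k` the tone's
#' index within its train (tones whose effect windows chain). Effects of
#' overlapping tones multiply, so the marginal effect per tone is
#' non-increasing in `k`.
#'
#' @param fs sampling rate, Hz.
#' @param stage_sw_amplitude named vector, slow-oscillation amplitude in uV
#'   per stage. N3 > N2 > (N1, R, W) by construction.
#' @param sw_freq_band slow-oscillation frequency band, Hz.
#' @param sw_freq_tau,sw_freq_sigma Ornstein-Uhlenbeck parameters of the
#'   instantaneous frequency: relaxation time (s) and stationary SD (Hz).
#' @param stage_delta_amplitude named vector, SD in uV of the 2--5 Hz
#'   delta-band noise per stage (what the device's delta-band gates sense).
#' @param background_1f_scale SD in uV of the 1/f background.
#' @param background_1f_exponent spectral exponent alpha of the 1/f^alpha
#'   background power spectrum.
#' @param wake_alpha_amp,wake_beta_amp amplitude in uV of continuous 10 Hz
#'   alpha and 22 Hz beta activity added during wake.
#' @param arousal_rate arousal bursts per hour of sleep.
#' @param arousal_alpha_amp,arousal_beta_amp burst component amplitudes, uV.
#' @param artifact_rate high-amplitude artifact excursions per hour.
#' @param artifact_amp artifact peak amplitude, uV (> 300 so the device's
#'   amplitude veto and offline artifact rejection trip).
#' @param response_gain unitless evoked-response gain `g` (>= 0; 0 disables
#'   the response so tones and silence are statistically indistinguishable).
#' @param response_saturation per-tone decay `r` of the marginal gain, in
#'   `[0,1]`.
#' @param response_duration number of slow-wave cycles affected per tone.
#' @return a list of class `gen_params`.
#' @export
gen_params <- function(fs = 250,
                       stage_sw_amplitude = c(W = 5, N1 = 15, N2 = 40, N3 = 75, R = 10),
                       sw_freq_band = c(0.75, 1.25),
                       sw_freq_tau = 10,
                       sw_freq_sigma = 0.12,
                       stage_delta_amplitude = c(W = 3, N1 = 8, N2 = 20, N3 = 30, R = 4),
                       background_1f_scale = 10,
                       background_1f_exponent = 1,
                       wake_alpha_amp = 12,
                       wake_beta_amp = 6,
                       arousal_rate = 5,
                       arousal_alpha_amp = 15,
                       arousal_beta_amp = 8,
                       artifact_rate = 2,
                       artifact_amp = 400,
                       response_gain = 0.3,
                       response_saturation = 0.7,
                       response_duration = 4) {
  p <- list(fs = fs,
            stage_sw_amplitude = stage_sw_amplitude[STAGE_LEVELS],
            sw_freq_band = sw_freq_band,
            sw_freq_tau = sw_freq_tau,
            sw_freq_sigma = sw_freq_sigma,
            stage_delta_amplitude = stage_delta_amplitude[STAGE_LEVELS],
            background_1f_scale = background_1f_scale,
            background_1f_exponent = background_1f_exponent,
            wake_alpha_amp = wake_alpha_amp,
            wake_beta_amp = wake_beta_amp,
            arousal_rate = arousal_rate,
            arousal_alpha_amp = arousal_alpha_amp,
            arousal_beta_amp = arousal_beta_amp,
            artifact_rate = artifact_rate,
            artifact_amp = artifact_amp,
            response_gain = response_gain,
            response_saturation = response_saturation,
            response_duration = response_duration)
  validate_gen_params(p)
  class(p) <- "gen_params"
  p
}

validate_gen_params <- function(p) {
  stopifnot(p$fs > 0,
            length(p$sw_freq_band) == 2L,
            p$sw_freq_band[1] > 0, p$sw_freq_band[1] < p$sw_freq_band[2],
            all(p$stage_sw_amplitude >= 0),
            all(p$stage_delta_amplitude >= 0),
            p$background_1f_scale >= 0,
            p$response_gain >= 0,
            p$response_saturation >= 0, p$response_saturation <= 1,
            p$response_duration > 0,
            p$arousal_rate >= 0, p$artifact_rate >= 0)
  if (anyNA(p$stage_sw_amplitude) || anyNA(p$stage_delta_amplitude))
    stop("stage amplitude vectors must name all of W, N1, N2, N3, R")
  invisible(p)
}

#' @export
print.gen_params <- function(x, ...) {
  cat("<gen_params>\n")
  cat(sprintf("  fs %g Hz; slow oscillation %g-%g Hz, amp (uV) %s\n",
              x$fs, x$sw_freq_band[1], x$sw_freq_band[2],
              paste(sprintf("%s=%g", names(x$stage_sw_amplitude),
                            x$stage_sw_amplitude), collapse = " ")))
  cat(sprintf("  response: g=%g r=%g over %g cycles\n",
              x$response_gain, x$response_saturation, x$response_duration))
  invisible(x)
}

#' Simulate a study cohort design
#'
#' Draws per-subject generator parameters from strong/weak responder-class
#' distributions and lays out the night design: subjects x conditions x
#' approaches x nights, each with its own derived seed. Night signals are
#' realized lazily with [generate_night()]; the returned design table carries
#' everything needed to reproduce each night bit-for-bit.
#'
#' @param n_subjects number of subjects.
#' @param responder_mix named counts `c(strong = ..., weak = ...)`; must sum
#'   to `n_subjects`.
#' @param nights_per_condition nights per subject in each condition/approach
#'   cell.
#' @param conditions subset of `c("verum", "sham")`.
#' @param approaches subset of `c("windowed", "continuous")`.
#' @param g_range_strong,g_range_weak response-gain sampling ranges for the
#'   two classes (disjoint by default so the planted trait is recoverable).
#' @param age_mean_strong,age_mean_weak,age_sd subject age model (years);
#'   strong responders are drawn younger, mirroring the demographic the
#'   responder analysis probes.
#' @param base_params baseline [gen_params()] shared by all subjects.
#' @param seed integer seed; the whole design is a pure function of it.
#' @return list of class `cohort` with elements `subjects` (metadata
#'   data.frame: subject, class, g, r, age, sex) and `nights` (design
#'   data.frame: subject, class, condition, approach, night, seed).
#' @export
generate_cohort <- function(n_subjects = 8,
                            responder_mix = c(strong = 4, weak = 4),
                            nights_per_condition = 3,
                            conditions = c("verum", "sham"),
                            approaches = "windowed",
                            g_range_strong = c(0.25, 0.35),
                            g_range_weak = c(0.05, 0.10),
                            age_mean_strong = 65.5, age_mean_weak = 73.5,
                            age_sd = 2.5,
                            base_params = gen_params(),
                            seed = 1L) {
  stopifnot(n_subjects >= 1, nights_per_condition >= 1)
  if (sum(responder_mix) != n_subjects)
    stop("responder_mix must sum to n_subjects")
  conditions <- match.arg(conditions, c("verum", "sham"), several.ok = TRUE)
  approaches <- match.arg(approaches, c("windowed", "continuous"),
                          several.ok = TRUE)
  with_seed(seed, {
    cls <- rep(c("strong", "weak"),
               c(responder_mix[["strong"]] %||% 0, responder_mix[["weak"]] %||% 0))
    g <- ifelse(cls == "strong",
                runif(n_subjects, g_range_strong[1], g_range_strong[2]),
                runif(n_subjects, g_range_weak[1], g_range_weak[2]))
    age <- round(rnorm(n_subjects,
                       ifelse(cls == "strong", age_mean_strong, age_mean_weak),
                       age_sd), 1)
    sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      class = cls, g = g, r = base_params$response_saturation,
      age = age, sex = sex, stringsAsFactors = FALSE)
    nights <- expand.grid(night = seq_len(nights_per_condition),
                          approach = approaches, condition = conditions,
                          subject = subjects$subject,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    nights <- nights[, c("subject", "condition", "approach", "night")]
    nights <- nights[order(nights$subject, nights$condition,
                           nights$approach, nights$night), ]
    rownames(nights) <- NULL
    nights$class <- subjects$class[match(nights$subject, subjects$subject)]
    nights$seed <- vapply(seq_len(nrow(nights)), function(i)
      child_seed(seed, nights$subject[i], nights$condition[i],
                 nights$approach[i], nights$night[i]), integer(1))
    structure(list(subjects = subjects, nights = nights,
                   base_params = base_params, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d night sources\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$class),
                            names(table(x$subjects$class))), collapse = ", "),
              nrow(x$nights)))
  invisible(x)
}

# gen_params for one cohort subject: base params with the subject's gain.
subject_params <- function(cohort, subject) {
  row <- cohort$subjects[cohort$subjects$subject == subject, ]
  if (nrow(row) != 1L) stop("unknown subject: ", subject)
  p <- cohort$base_params
  p$response_gain <- row$g
  p
}
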