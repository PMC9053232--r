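#' Welch power spectral density
#'
#' Welch's averaged-periodogram PSD with Hamming-tapered segments. With the
#' defaults (4-s segments at 50% overlap) a 6-s epoch at 250 Hz yields two
#' segments and 0.25 Hz bin spacing. Scaling is the one-sided density
#' convention: `sum(psd) * df` equals the signal variance captured up to the
#' Nyquist frequency (a unit-amplitude sinusoid integrates to 0.5 uV^2).
#'
#' @param x samples, uV.
#' @param fs sampling rate, Hz.
#' @param window_sec segment length, seconds.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 4, overlap = 0.5) {
  W <- round(window_sec * fs)
  if (length(x) < W) stop("signal shorter than one Welch segment")
  step <- max(1L, round(W * (1 - overlap)))
  starts <- seq(1L, length(x) - W + 1L, by = step)
  i <- 0:(W - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * i / (W - 1L))
  segs <- vapply(starts, function(s) x[s:(s + W - 1L)] * w, numeric(W))
  P <- Mod(mvfft(segs))^2
  nfreq <- floor(W / 2) + 1L
  pxx <- rowMeans(P)[seq_len(nfreq)] / (fs * sum(w^2))
  one_sided <- rep(2, nfreq)
  one_sided[1] <- 1
  if (W %% 2 == 0) one_sided[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / W, psd = pxx * one_sided)
}

#' Per-epoch spectrum of a 6-s EEG epoch
#'
#' Thin, length-checked wrapper around [welch_psd()] for the pipeline's 6-s
#' analysis epochs (1500 samples at 250 Hz): 4-s Hamming segments, 50%
#' overlap, 0.25 Hz bins.
#'
#' @param x exactly `6 * fs` samples.
#' @param fs sampling rate, Hz.
#' @param epoch_start epoch onset, seconds from recording start.
#' @return object of class `epoch_spectrum`: list `freq`, `psd`, plus
#'   bookkeeping fields `epoch_start`, `normalized`.
#' @export
epoch_psd <- function(x, fs = 250, epoch_start = NA_real_) {
  if (length(x) != round(6 * fs))
    stop(sprintf("epoch must have exactly %d samples, got %d",
                 round(6 * fs), length(x)))
  sp <- welch_psd(x, fs, window_sec = 4, overlap = 0.5)
  structure(list(freq = sp$freq, psd = sp$psd, epoch_start = epoch_start,
                 normalized = FALSE),
            class = "epoch_spectrum")
}

#' Normalize a spectrum by its cumulative power up to 30 Hz
#'
#' Converts the spectrum to unitless bin powers divided by the summed bin
#' power from the lowest bin through 30 Hz inclusive, so the bins up to
#' 30 Hz sum to exactly 1. Scale-invariant, and idempotent on an already
#' normalized spectrum.
#'
#' @param spec an `epoch_spectrum` (or list with `freq`, `psd`).
#' @param ceiling_hz normalization ceiling, Hz.
#' @return the spectrum with `psd` replaced by normalized bin powers and
#'   `normalized = TRUE`.
#' @export
normalize_psd <- function(spec, ceiling_hz = 30) {
  df <- spec$freq[2] - spec$freq[1]
  binp <- if (isTRUE(spec$normalized)) spec$psd else spec$psd * df
  denom <- sum(binp[spec$freq <= ceiling_hz])
  if (denom <= 0) stop("cumulative power up to the ceiling is zero")
  spec$psd <- binp / denom
  spec$normalized <- TRUE
  spec
}

#' Low-frequency slow-wave activity of a spectrum
#'
#' Integrated band power over the bins whose centers lie in the
#' low-frequency slow-wave range (0.75--1.25 Hz, endpoints inclusive). On an
#' absolute spectrum the unit is uV^2 (bin PSD times bin width, summed); on
#' a normalized spectrum the result is a unitless fraction.
#'
#' @param spec an `epoch_spectrum`.
#' @param band frequency band, Hz.
#' @return scalar band power.
#' @export
compute_low_swa <- function(spec, band = c(0.75, 1.25)) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= band[1] - 1e-9 & spec$freq <= band[2] + 1e-9
  if (isTRUE(spec$normalized)) sum(spec$psd[sel]) else sum(spec$psd[sel]) * df
}

# fast path: lowSWA for every column of a samples-by-epochs matrix
low_swa_matrix <- function(segmat, fs, band = c(0.75, 1.25)) {
  W <- round(4 * fs)
  n <- nrow(segmat)
  stopifnot(n == round(6 * fs))
  i <- 0:(W - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * i / (W - 1L))
  scale <- 1 / (fs * sum(w^2))
  df <- fs / W
  freqs <- (seq_len(floor(W / 2) + 1L) - 1L) * df
  sel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  p1 <- Mod(mvfft(segmat[1:W, , drop = FALSE] * w))^2
  p2 <- Mod(mvfft(segmat[(n - W + 1L):n, , drop = FALSE] * w))^2
  pxx <- (p1[sel, , drop = FALSE] + p2[sel, , drop = FALSE]) / 2 * scale * 2
  colSums(pxx) * df
}
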