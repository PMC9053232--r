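#' Zero-phase offline band-pass filter (0.5--40 Hz)
#'
#' Offline (non-causal) filtering used before all spectral analysis:
#' forward-backward Butterworth high-pass at 0.5 Hz (3rd order) and low-pass
#' at 40 Hz (4th order), giving zero phase distortion and effectively doubled
#' order.
#'
#' @param x samples, uV.
#' @param fs sampling rate, Hz.
#' @param hp,lp corner frequencies, Hz.
#' @return filtered samples.
#' @export
offline_filter <- function(x, fs = 250, hp = 0.5, lp = 40) {
  if (length(x) < 9 * fs)
    stop("signal too short for the offline filter warm-up")
  bh <- signal::butter(3, hp / (fs / 2), type = "high")
  bl <- signal::butter(4, lp / (fs / 2), type = "low")
  y <- signal::filtfilt(bh, as.numeric(x))
  as.numeric(signal::filtfilt(bl, y))
}

#' Select 6-s analysis epochs and count stimulations
#'
#' Tiles the recording into consecutive 6-s epochs from recording start and
#' applies the inclusion rule: an epoch is included iff (a) both the device
#' NREM track and the hypnogram label its entire span N2 or N3 ("dual"
#' agreement), (b) it contains no artifact (amplitude above the 300 uV
#' ceiling or flagged QC second), and (c) its peak absolute amplitude is not
#' an outlier under the median +/- `outlier_k` scaled-MAD rule computed over
#' the night's dual-NREM epochs. Each epoch also receives the count of
#' logged stimulation events (tones and triggers) whose times fall in its
#' half-open span.
#'
#' @param run a `stim_run` from [run_night()] (or a list with `track`,
#'   `qc_sec`, `log`, `eeg`).
#' @param hyp the night's [hypnogram()].
#' @param config an [engine_config()].
#' @param outlier_k scaled-MAD multiplier of the outlier rule.
#' @return data.frame, one row per epoch: `epoch`, `start_s`, `dual_nrem`,
#'   `artifact`, `outlier`, `included`, `exclusion_reason`, `stim_count`,
#'   `peak_amp`, `window_label`.
#' @export
select_epochs <- function(run, hyp, config = run$config, outlier_k = 3) {
  fs <- config$fs
  eeg <- run$eeg
  epoch_len <- 6
  n_ep <- floor(length(eeg) / (epoch_len * fs))
  if (n_ep == 0L) stop("recording shorter than one 6-s epoch")
  start_s <- (seq_len(n_ep) - 1L) * epoch_len

  stages <- stage_track(hyp, 1)  # per-second stage codes
  n2n3 <- stages %in% c(3L, 4L)
  track <- run$track
  dev_nrem <- track$nrem == 1L
  qc_bad <- as.logical(run$qc_sec)
  win_sec <- track$window  # 0 none / 1 ON / 2 OFF per second

  sec_idx <- function(e) (start_s[e] + 1L):(start_s[e] + epoch_len)
  all_true <- function(v, idx) all(idx <= length(v)) && all(v[idx])

  segmat <- matrix(eeg[seq_len(n_ep * epoch_len * fs)], nrow = epoch_len * fs)
  peak <- apply(abs(segmat), 2, max)

  dual <- vapply(seq_len(n_ep), function(e) {
    idx <- sec_idx(e)
    all_true(n2n3, idx) && all_true(dev_nrem, idx)
  }, logical(1))
  artifact <- vapply(seq_len(n_ep), function(e) {
    idx <- sec_idx(e)
    peak[e] > config$amplitude_ceiling || any(qc_bad[idx[idx <= length(qc_bad)]])
  }, logical(1))

  med <- median(peak[dual & !artifact])
  madv <- mad(peak[dual & !artifact])
  outlier <- peak > med + outlier_k * madv | peak < med - outlier_k * madv

  ev_t <- run$log$t_s
  stim_count <- if (length(ev_t))
    tabulate(findInterval(ev_t, c(start_s, start_s[n_ep] + epoch_len)),
             nbins = n_ep) else integer(n_ep)

  wlab <- vapply(seq_len(n_ep), function(e) {
    idx <- sec_idx(e)
    idx <- idx[idx <= length(win_sec)]
    w <- unique(win_sec[idx])
    if (length(w) == 1L) c("NA", "ON", "OFF")[w + 1L] else "NA"
  }, character(1))

  reason <- ifelse(!dual, "not_dual_NREM",
                   ifelse(artifact, "artifact",
                          ifelse(outlier, "outlier", "none")))
  data.frame(epoch = seq_len(n_ep) - 1L, start_s = start_s,
             dual_nrem = dual, artifact = artifact, outlier = outlier,
             included = reason == "none", exclusion_reason = reason,
             stim_count = stim_count, peak_amp = peak, window_label = wlab,
             stringsAsFactors = FALSE)
}

# per-epoch table with lowSWA of the offline-filtered signal
night_epoch_table <- function(run, hyp, config = run$config, outlier_k = 3,
                              band = c(0.75, 1.25)) {
  ep <- select_epochs(run, hyp, config, outlier_k)
  fs <- config$fs
  filt <- offline_filter(run$eeg, fs)
  segmat <- matrix(filt[seq_len(nrow(ep) * 6 * fs)], nrow = 6 * fs)
  ep$lowswa <- low_swa_matrix(segmat, fs, band)
  ep
}

#' Consecutive 6-s epoch analysis
#'
#' The "consecutive" analysis path, applicable to both approaches: the whole
#' recording is tiled into consecutive 6-s epochs, each epoch gets its
#' inclusion flags, stimulation count, and lowSWA of the offline-filtered
#' signal; the subset with more than two stimulations is marked.
#'
#' @inheritParams select_epochs
#' @param hyp the night's hypnogram.
#' @return the epoch table of [select_epochs()] with columns `lowswa` and
#'   `gt2` (more than 2 stimulations) added.
#' @export
consecutive_stim_epochs <- function(run, hyp, config = run$config,
                                    outlier_k = 3) {
  ep <- night_epoch_table(run, hyp, config, outlier_k)
  ep$gt2 <- ep$stim_count > 2L
  ep
}

#' Low slow-wave energy of a night
#'
#' lowSWA summed over all included NREM epochs of the night ("energy").
#'
#' @param epochs an epoch table with `included` and `lowswa` columns (see
#'   [consecutive_stim_epochs()]).
#' @return scalar, uV^2 summed over epochs.
#' @export
compute_low_swe <- function(epochs) {
  if (nrow(epochs) == 0L) return(0)
  sum(epochs$lowswa[epochs$included])
}

#' ON--OFF window contrast with stimulation-count binning
#'
#' The windowed-approach analysis: every 6-s ON and OFF window scheduled by
#' the device that (a) lies entirely in dual-detected NREM, (b) has no
#' artifact/outlier/beta-veto content, and (c) contains at least one logged
#' stimulation (tone, or trigger/marker), contributes its lowSWA. Windows
#' are binned by their own stimulation count (1--2, 3--4, >4; OFF windows by
#' their marker count), and per-night per-bin means and ON - OFF differences
#' are returned, together with the >2-stimulation aggregate.
#'
#' @param run a `stim_run` with `approach == "windowed"`.
#' @param hyp the night's hypnogram.
#' @param config an [engine_config()].
#' @param outlier_k scaled-MAD multiplier for window peak amplitudes.
#' @return list with `bins` (data.frame: `bin`, `mean_on`, `mean_off`,
#'   `diff`, `n_on`, `n_off`), `gt2` (the same summary for the union of the
#'   3--4 and >4 bins), and `windows` (the per-window table).
#' @export
onoff_contrast <- function(run, hyp, config = run$config, outlier_k = 3) {
  if (config$approach != "windowed")
    stop("ON-OFF contrast requires a windowed-approach night; ",
         "use consecutive_stim_epochs() for continuous nights")
  fs <- config$fs
  track <- run$track
  win <- track$window
  # contiguous runs of ON/OFF seconds -> windows
  r <- rle(win)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c(1L, 2L) & r$lengths == config$window_len
  if (!any(keep))
    return(list(bins = empty_bins(), gt2 = NULL,
                windows = data.frame()))
  wstart <- track$second[starts[keep]]
  wlabel <- ifelse(r$values[keep] == 1L, "ON", "OFF")

  stages <- stage_track(hyp, 1)
  n2n3 <- stages %in% c(3L, 4L)
  dev_nrem <- track$nrem == 1L
  beta <- track$beta_veto == 1L
  qc_bad <- as.logical(run$qc_sec)

  filt <- offline_filter(run$eeg, fs)
  ev_t <- run$log$t_s

  rows <- lapply(seq_along(wstart), function(i) {
    s0 <- wstart[i]
    secs <- (s0 + 1L):(s0 + config$window_len)
    if (max(secs) > length(n2n3) || max(secs) > nrow(track)) return(NULL)
    samp <- (s0 * fs + 1L):((s0 + config$window_len) * fs)
    if (max(samp) > length(filt)) return(NULL)
    seg <- filt[samp]
    peak <- max(abs(run$eeg[samp]))
    data.frame(start_s = s0, label = wlabel[i],
               dual = all(n2n3[secs]) && all(dev_nrem[secs]),
               clean = !any(beta[secs]) && !any(qc_bad[secs]) &&
                 peak <= config$amplitude_ceiling,
               peak = peak,
               stim_count = sum(ev_t >= s0 & ev_t < s0 + config$window_len),
               lowswa = low_swa_matrix(matrix(seg, ncol = 1), fs)[1],
               stringsAsFactors = FALSE)
  })
  wdf <- do.call(rbind, rows)
  if (is.null(wdf) || nrow(wdf) == 0L)
    return(list(bins = empty_bins(), gt2 = NULL, windows = data.frame()))
  cand <- wdf$dual & wdf$clean
  med <- median(wdf$peak[cand]); madv <- mad(wdf$peak[cand])
  wdf$outlier <- wdf$peak > med + outlier_k * madv |
    wdf$peak < med - outlier_k * madv
  wdf$included <- cand & !wdf$outlier & wdf$stim_count >= 1L
  wdf$bin <- stim_bin(wdf$stim_count)

  summarize <- function(sub) {
    per_bin <- function(b) {
      on <- sub$lowswa[sub$bin == b & sub$label == "ON"]
      off <- sub$lowswa[sub$bin == b & sub$label == "OFF"]
      data.frame(bin = b, mean_on = mean(on), mean_off = mean(off),
                 diff = mean(on) - mean(off),
                 n_on = length(on), n_off = length(off))
    }
    do.call(rbind, lapply(c("1-2", "3-4", ">4"), per_bin))
  }
  inc <- wdf[wdf$included, ]
  bins <- summarize(inc)
  g <- inc[inc$stim_count > 2L, ]
  gt2 <- data.frame(
    bin = ">2",
    mean_on = mean(g$lowswa[g$label == "ON"]),
    mean_off = mean(g$lowswa[g$label == "OFF"]),
    diff = mean(g$lowswa[g$label == "ON"]) - mean(g$lowswa[g$label == "OFF"]),
    n_on = sum(g$label == "ON"), n_off = sum(g$label == "OFF"))
  list(bins = bins, gt2 = gt2, windows = wdf)
}

empty_bins <- function() {
  data.frame(bin = c("1-2", "3-4", ">4"), mean_on = NaN, mean_off = NaN,
             diff = NaN, n_on = 0L, n_off = 0L)
}

# stimulation-count bins: 1-2, 3-4, >4 (counts of 0 get NA)
stim_bin <- function(count) {
  out <- rep(NA_character_, length(count))
  out[count >= 1 & count <= 2] <- "1-2"
  out[count >= 3 & count <= 4] <- "3-4"
  out[count > 4] <- ">4"
  out
}

#' Event-locked evoked responses
#'
#' Averages the offline-filtered EEG around event times, with baseline
#' correction by the mean of the 0.5 s preceding each event. Only events
#' whose full window lies inside the recording contribute.
#'
#' @param signal offline-filtered EEG (uV) or a raw vector to filter when
#'   `filter = TRUE`.
#' @param events event times, seconds.
#' @param fs sampling rate, Hz.
#' @param window `c(pre, post)` seconds around each event.
#' @param baseline_sec pre-event baseline length for correction, s.
#' @param filter apply [offline_filter()] first?
#' @return list with `time` (s relative to the event), `erp` (mean uV),
#'   `n` (events averaged); `n = 0` with empty curves when no event
#'   qualifies.
#' @export
evoked_response <- function(signal, events, fs = 250, window = c(-1, 3),
                            baseline_sec = 0.5, filter = FALSE) {
  if (filter) signal <- offline_filter(signal, fs)
  pre <- round(-window[1] * fs); post <- round(window[2] * fs)
  len <- pre + post + 1L
  idx0 <- round(events * fs) + 1L
  ok <- idx0 - pre >= 1L & idx0 + post <= length(signal)
  idx0 <- idx0[ok]
  if (length(idx0) == 0L)
    return(list(time = numeric(0), erp = numeric(0), n = 0L))
  mat <- vapply(idx0, function(i) signal[(i - pre):(i + post)], numeric(len))
  nb <- round(baseline_sec * fs)
  base <- colMeans(mat[(pre - nb + 1L):pre, , drop = FALSE])
  mat <- sweep(mat, 2, base)
  list(time = ((-pre):post) / fs, erp = rowMeans(mat), n = length(idx0))
}

#' @rdname evoked_response
#' @param erp_on,erp_off results of `evoked_response()` for ON and OFF
#'   events on a shared time base.
#' @return `erp_difference`: list `time`, `erp` (ON minus OFF).
#' @export
erp_difference <- function(erp_on, erp_off) {
  stopifnot(length(erp_on$time) == length(erp_off$time))
  list(time = erp_on$time, erp = erp_on$erp - erp_off$erp)
}

#' Sleep architecture summary
#'
#' Stage percentages of total sleep time, sleep latency (time from recording
#' start to the first epoch of any sleep stage), and wake/TST bookkeeping.
#'
#' @param hyp a [hypnogram()].
#' @return list: `pct` (named percentages of total sleep time for N1, N2,
#'   N3, R; sums to 100 when any sleep exists), `pct_W` (wake as a
#'   percentage of the recording), `sleep_latency_min` (`NA` for an all-wake
#'   night), `rem_pct`, `tst_min`.
#' @export
sleep_architecture <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- attr(hyp, "epoch_length")
  stages <- unclass(hyp)
  sleep <- stages != "W"
  tst_min <- sum(sleep) * el / 60
  pct <- vapply(c("N1", "N2", "N3", "R"),
                function(s) 100 * sum(stages == s) / max(1L, sum(sleep)),
                numeric(1))
  first_sleep <- which(sleep)[1]
  list(pct = pct,
       pct_W = 100 * sum(!sleep) / length(stages),
       sleep_latency_min = if (is.na(first_sleep)) NA_real_
                           else (first_sleep - 1L) * el / 60,
       rem_pct = pct[["R"]],
       tst_min = tst_min)
}

#' Offline arousal detection
#'
#' Band-power arousal detector over scored sleep only: short-time alpha
#' (8--12 Hz) and beta (>16 Hz) power in 1-s windows stepped by 0.5 s; a
#' window is suprathreshold when either band exceeds the median plus
#' `k` scaled MADs of the surrounding 5 minutes of that band; runs of at
#' least `min_dur` s are events, and events separated by less than
#' `merge_gap` s merge.
#'
#' @param eeg EEG samples, uV (raw; filtered internally).
#' @param hyp the night's hypnogram (wake windows are excluded).
#' @param fs sampling rate, Hz.
#' @param k MAD multiplier of the adaptive threshold (default 6, chosen so
#'   clean synthetic NREM yields no false detections).
#' @param context_sec width of the rolling threshold context, s.
#' @param min_dur minimum event duration, s.
#' @param merge_gap merge gap, s.
#' @return data.frame with `onset_s` and `duration_s`, possibly empty.
#' @export
detect_arousals <- function(eeg, hyp, fs = 250, k = 6, context_sec = 300,
                            min_dur = 3, merge_gap = 3) {
  filt <- offline_filter(eeg, fs)
  step <- 0.5
  centers <- seq(0, length(eeg) / fs - 1, by = step)
  bands <- rbind(alpha = c(8, 12), beta = c(16, 40))
  pw <- vapply(centers, function(t0) {
    idx <- (round(t0 * fs) + 1L):min(length(filt), round((t0 + 1) * fs))
    seg <- filt[idx]
    W <- length(seg)
    X <- fft(seg)
    f <- (seq_len(W) - 1L) * fs / W
    vapply(seq_len(nrow(bands)), function(b) {
      sel <- f >= bands[b, 1] & f <= bands[b, 2]
      2 * sum(Mod(X[sel])^2) / W^2
    }, numeric(1))
  }, numeric(2))
  half <- round(context_sec / 2 / step)
  above <- rep(FALSE, length(centers))
  for (b in 1:2) {
    p <- pw[b, ]
    thr <- vapply(seq_along(p), function(i) {
      ctx <- p[max(1L, i - half):min(length(p), i + half)]
      median(ctx) + k * mad(ctx)
    }, numeric(1))
    above <- above | (p > thr)
  }
  stages <- stage_track(hyp, 1)
  sec <- pmin(length(stages), floor(centers) + 1L)
  above[stages[sec] == 1L] <- FALSE  # wake excluded

  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- data.frame(onset_s = centers[starts[r$values]],
                   end_s = centers[ends[r$values]] + 1)
  if (nrow(ev) > 1L) {  # merge close events
    keep <- ev[1, ]
    for (i in 2:nrow(ev)) {
      if (ev$onset_s[i] - keep$end_s[nrow(keep)] < merge_gap)
        keep$end_s[nrow(keep)] <- ev$end_s[i]
      else keep <- rbind(keep, ev[i, ])
    }
    ev <- keep
  }
  ev$duration_s <- ev$end_s - ev$onset_s
  ev <- ev[ev$duration_s >= min_dur, c("onset_s", "duration_s")]
  rownames(ev) <- NULL
  ev
}

#' Night-level quality control
#'
#' A night is excluded when more than `limit_min` minutes of bad signal were
#' flagged or the recording is partial (truncated).
#'
#' @param qc_sec per-second bad-signal flags.
#' @param truncated was the recording truncated / partial?
#' @param limit_min exclusion threshold, minutes.
#' @return list `keep` (logical) and `reason` (`"ok"`, `"bad_signal"`, or
#'   `"partial_recording"`).
#' @export
night_qc <- function(qc_sec, truncated = FALSE, limit_min = 20) {
  if (isTRUE(truncated))
    return(list(keep = FALSE, reason = "partial_recording"))
  bad_min <- sum(as.logical(qc_sec)) / 60
  if (bad_min > limit_min)
    return(list(keep = FALSE, reason = "bad_signal"))
  list(keep = TRUE, reason = "ok")
}
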