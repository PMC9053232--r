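# A compact synthetic "run" built by hand so selection logic can be tested
# against brute-force expectations without the full engine.
make_toy_run <- function(eeg, nrem_sec, stim_times = numeric(0),
                         window_sec = NULL, qc_sec = NULL, fs = 250) {
  nsec <- floor(length(eeg) / fs)
  track <- data.frame(second = 0:(nsec - 1),
                      nrem = as.integer(seq_len(nsec) %in% (nrem_sec + 1)),
                      sws = 0L, beta_veto = 0L, stim_enabled = 0L,
                      window = if (is.null(window_sec)) 0L else window_sec,
                      volume_db = 52)
  nl <- length(stim_times)
  log <- data.frame(t_s = stim_times, kind = rep("tone", nl),
                    volume_db = rep(52, nl), phase_est_deg = rep(45, nl),
                    window_label = rep("NA", nl),
                    window_index = rep(NA_integer_, nl),
                    stringsAsFactors = FALSE)
  cfg <- fx_plain_config()
  structure(list(log = log, track = track,
                 qc_sec = if (is.null(qc_sec)) rep(FALSE, nsec) else qc_sec,
                 eeg = eeg, baseline_window = NULL, config = cfg),
            class = "stim_run")
}

test_that("epoch selection enforces dual-NREM, artifact, and counting rules", {
  fs <- 250
  set.seed(21)
  eeg <- rnorm(60 * fs, 0, 20)
  hyp <- hypnogram(c("N3", "N3", "W"))  # 60 s: N3 for 40 s, W for 20 s
  # device agrees on NREM everywhere; hypnogram disagrees in the last 20 s
  run <- make_toy_run(eeg, nrem_sec = 0:59)
  ep <- select_epochs(run, hyp, run$config)
  expect_equal(nrow(ep), 10)
  expect_true(all(ep$exclusion_reason[ep$start_s >= 42] == "not_dual_NREM"))
  expect_true(all(ep$dual_nrem[ep$start_s + 6 <= 40]))

  # device-side disagreement alone excludes
  run2 <- make_toy_run(eeg, nrem_sec = 12:59)
  ep2 <- select_epochs(run2, hyp, run2$config)
  expect_equal(ep2$exclusion_reason[1], "not_dual_NREM")

  # a 350 uV artifact excludes its epoch
  eeg3 <- eeg; eeg3[10 * fs] <- 350
  ep3 <- select_epochs(make_toy_run(eeg3, 0:59), hyp, run$config)
  expect_equal(ep3$exclusion_reason[ep3$start_s == 6], "artifact")

  # stimulation counting vs brute-force interval membership
  run4 <- make_toy_run(eeg, 0:59, stim_times = c(3.1, 4.0, 17, 18, 19))
  ep4 <- select_epochs(run4, hyp, run4$config)
  expect_equal(ep4$stim_count[ep4$start_s == 0], 2)
  expect_equal(ep4$stim_count[ep4$start_s == 12], 1)  # event at 17 s
  expect_equal(ep4$stim_count[ep4$start_s == 18], 2)  # events at 18, 19 s
  expect_equal(sum(ep4$stim_count), 5)
})

test_that("consecutive tiling counts stimulations like a brute-force scan", {
  fs <- 250
  set.seed(22)
  eeg <- rnorm(60 * fs, 0, 20)
  hyp <- hypnogram(c("N3", "N3", "N3"))
  run <- make_toy_run(eeg, 0:59, stim_times = c(5, 17, 18, 19))
  ep <- consecutive_stim_epochs(run, hyp, run$config)
  brute <- vapply(ep$start_s, function(s0)
    sum(run$log$t_s >= s0 & run$log$t_s < s0 + 6), integer(1))
  expect_identical(ep$stim_count, brute)
  expect_identical(ep$gt2, ep$stim_count > 2)
  # no events -> empty >2 subset
  ep0 <- consecutive_stim_epochs(make_toy_run(eeg, 0:59), hyp, run$config)
  expect_false(any(ep0$gt2))
})

test_that("lowSWE is the plain sum of included-epoch lowSWA", {
  ep <- data.frame(included = c(TRUE, TRUE, TRUE), lowswa = c(1, 2, 3))
  expect_equal(compute_low_swe(ep), 6)
  expect_equal(compute_low_swe(ep[0, ]), 0)
  set.seed(9)
  ep2 <- data.frame(included = runif(50) > 0.3, lowswa = rexp(50))
  expect_equal(compute_low_swe(ep2), sum(ep2$lowswa[ep2$included]),
               tolerance = 1e-12)
})

test_that("ON-OFF contrast reproduces hand-computed per-bin means", {
  fs <- 250
  # six windows: ON/OFF alternating, 36 s of N3, controlled lowSWA per
  # window via a 1 Hz sinusoid of chosen amplitude
  amps <- c(10, 6, 8, 5, 12, 7)    # window lowSWA ~ amp^2/2
  counts <- c(2, 2, 3, 3, 5, 5)    # stim counts per window
  t <- (0:(36 * fs - 1)) / fs
  eeg <- numeric(length(t))
  for (w in 1:6) {
    idx <- ((w - 1) * 6 * fs + 1):(w * 6 * fs)
    eeg[idx] <- amps[w] * sin(2 * pi * 1 * t[idx])
  }
  stim <- unlist(lapply(1:6, function(w)
    (w - 1) * 6 + seq(0.5, by = 1.1, length.out = counts[w])))
  window_sec <- rep(rep(c(1L, 2L), 3), each = 6)
  hyp <- hypnogram(c("N3", "N3"), epoch_length = 18)
  run <- make_toy_run(eeg, 0:35, stim_times = stim, window_sec = window_sec)
  res <- onoff_contrast(run, hyp, run$config)
  w <- res$windows
  expect_equal(nrow(w), 6)
  expect_equal(w$stim_count, counts)
  # hand-computed means per bin (ON windows 1,3,5; OFF windows 2,4,6)
  lw <- w$lowswa
  expect_equal(res$bins$diff[res$bins$bin == "1-2"], lw[1] - lw[2],
               tolerance = 1e-9)
  expect_equal(res$bins$diff[res$bins$bin == "3-4"], lw[3] - lw[4],
               tolerance = 1e-9)
  expect_equal(res$bins$diff[res$bins$bin == ">4"], lw[5] - lw[6],
               tolerance = 1e-9)
  expect_equal(res$gt2$diff, mean(lw[c(3, 5)]) - mean(lw[c(4, 6)]),
               tolerance = 1e-9)
  # the window lowSWA itself tracks the planted amplitudes
  expect_equal(order(lw), order(amps^2))
  # continuous nights are rejected
  cfg_cont <- fx_plain_config(approach = "continuous")
  run_cont <- run; run_cont$config <- cfg_cont
  expect_error(onoff_contrast(run_cont, hyp, cfg_cont), "windowed")
})

test_that("evoked responses recover a planted template and null out", {
  fs <- 250
  set.seed(33)
  n <- 120 * fs
  eeg <- rnorm(n, 0, 1)
  tmpl <- 5 * sin(2 * pi * 2 * (0:(fs / 2 - 1)) / fs)  # 0.5-s burst
  events <- seq(5, 110, by = 2.5)
  for (e in events) {
    i <- round(e * fs) + 1
    eeg[i:(i + length(tmpl) - 1)] <- eeg[i:(i + length(tmpl) - 1)] + tmpl
  }
  erp <- evoked_response(eeg, events, fs)
  expect_equal(erp$n, length(events))
  at <- function(tt) erp$erp[which.min(abs(erp$time - tt))]
  # peak of the template at t = 0.125 s recovered within noise/sqrt(n)
  expect_lt(abs(at(0.125) - 5) , 5 * 3 / sqrt(length(events)))
  # zero signal -> zero ERP; identical ON/OFF -> zero difference
  erp0 <- evoked_response(numeric(n), events, fs)
  expect_true(all(erp0$erp == 0))
  d <- erp_difference(erp, erp)
  expect_true(all(d$erp == 0))
  # no qualifying events
  none <- evoked_response(eeg, numeric(0), fs)
  expect_equal(none$n, 0)
})

test_that("arousal detection finds planted bursts and spares clean sleep", {
  fs <- 250
  p <- gen_params(arousal_rate = 0, artifact_rate = 0)
  hyp <- generate_hypnogram(stage_bouts("N2", 10))
  night <- generate_night(hyp, p, seed = 17)
  # plant one 5-s alpha burst at 300 s
  eeg <- night$eeg
  idx <- (300 * fs):(305 * fs)
  eeg[idx] <- eeg[idx] + 40 * sin(2 * pi * 10 * (idx / fs))
  ev <- detect_arousals(eeg, hyp, fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 300), 5)
  # clean night: no events
  ev0 <- detect_arousals(night$eeg, hyp, fs)
  expect_equal(nrow(ev0), 0)
  # the same burst during wake is ignored
  hyp_w <- generate_hypnogram(stage_bouts("W", 10))
  night_w <- generate_night(hyp_w, p, seed = 17)
  eeg_w <- night_w$eeg
  eeg_w[idx] <- eeg_w[idx] + 40 * sin(2 * pi * 10 * (idx / fs))
  ev_w <- detect_arousals(eeg_w, hyp_w, fs)
  expect_equal(nrow(ev_w), 0)
})

test_that("night QC applies the 20-minute and completeness rules", {
  expect_false(night_qc(rep(TRUE, 21 * 60))$keep)    # 21 min bad
  expect_true(night_qc(rep(TRUE, 19 * 60))$keep)     # 19 min bad
  expect_equal(night_qc(logical(100), truncated = TRUE)$reason,
               "partial_recording")
  expect_equal(night_qc(rep(TRUE, 21 * 60))$reason, "bad_signal")
})
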