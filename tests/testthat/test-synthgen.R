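test_that("a slow-oscillation-only night concentrates its power in band", {
  p <- gen_params(stage_delta_amplitude = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                  background_1f_scale = 0, wake_alpha_amp = 0,
                  wake_beta_amp = 0, arousal_rate = 0, artifact_rate = 0)
  night <- generate_night(generate_hypnogram(stage_bouts("N3", 2)), p, seed = 3)
  seg <- night$eeg[2501:4000]  # one 6-s excerpt past any edge
  sp <- epoch_psd(seg, 250)
  df <- sp$freq[2] - sp$freq[1]
  in_band <- sum(sp$psd[sp$freq >= 0.75 & sp$freq <= 1.25]) * df
  total30 <- sum(sp$psd[sp$freq <= 30]) * df
  expect_gt(in_band / total30, 0.90)
})

test_that("ground-truth phase hits 90 deg at every positive slow-wave peak", {
  p <- gen_params(stage_delta_amplitude = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                  background_1f_scale = 0, arousal_rate = 0, artifact_rate = 0)
  night <- generate_night(generate_hypnogram(stage_bouts("N3", 2)), p, seed = 11)
  sw <- night$eeg
  peaks <- which(diff(sign(diff(sw))) == -2) + 1L
  peaks <- peaks[sw[peaks] > 0]
  ph <- ground_truth_phase_deg(night)[peaks]
  expect_true(all(abs(circ_diff_deg(ph, 90)) < 1))
})

test_that("slow-wave band power orders by stage as constructed", {
  p <- fx_params()
  lowswa_of <- function(stage) {
    night <- generate_night(generate_hypnogram(stage_bouts(stage, 2)), p,
                            seed = 5)
    mean(vapply(0:18, function(k)
      compute_low_swa(epoch_psd(night$eeg[(k * 1500 + 1):((k + 1) * 1500)])),
      numeric(1)))
  }
  expect_gt(lowswa_of("N3"), lowswa_of("N2"))
  expect_gt(lowswa_of("N2"), lowswa_of("W"))
})

test_that("pure 1/f background reproduces the configured spectral slope", {
  p <- gen_params(stage_sw_amplitude = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                  stage_delta_amplitude = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                  background_1f_scale = 10, background_1f_exponent = 1,
                  wake_alpha_amp = 0, wake_beta_amp = 0,
                  arousal_rate = 0, artifact_rate = 0)
  night <- generate_night(generate_hypnogram(stage_bouts("N3", 4)), p, seed = 2)
  sp <- welch_psd(night$eeg, 250, window_sec = 8)
  sel <- sp$freq >= 1 & sp$freq <= 30
  slope <- coef(lm(log(sp$psd[sel]) ~ log(sp$freq[sel])))[2]
  expect_lt(abs(-slope - p$background_1f_exponent), 0.1 * p$background_1f_exponent)
})

test_that("generated nights are a pure function of (template, params, seed)", {
  p <- fx_params()
  hyp <- generate_hypnogram(stage_bouts(c("N2", "N3"), c(2, 2)))
  a <- generate_night(hyp, p, seed = 99)
  b <- generate_night(hyp, p, seed = 99)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$events, b$events)
  expect_false(identical(a$eeg, generate_night(hyp, p, seed = 100)$eeg))
})

test_that("stimulus effects follow the saturating train rule exactly", {
  p <- gen_params(response_gain = 0.2, response_saturation = 1,
                  response_duration = 4,
                  stage_delta_amplitude = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                  background_1f_scale = 0, arousal_rate = 0, artifact_rate = 0)
  hyp <- generate_hypnogram(stage_bouts("N3", 2))
  night <- generate_night(hyp, p, seed = 8)
  v <- 52
  vw <- 0.8 + 0.4 * (v - 46) / 14

  # r = 1: three tones in one train -> cumulative multiplier (1 + g*v)^3
  res <- apply_stim_effects(night, times = c(10, 10.6, 11.2), volumes = v)
  expect_equal(max(res$multiplier), (1 + 0.2 * vw)^3, tolerance = 1e-12)

  # g = 0 leaves the signal untouched
  p0 <- p; p0$response_gain <- 0
  res0 <- apply_stim_effects(night, times = c(10, 11), params = p0)
  expect_identical(res0$eeg, night$eeg)
  expect_true(all(res0$multiplier == 1))

  # r = 0.5: marginal multipliers shrink geometrically; cross-check against
  # a brute-force per-stimulus replay of the update rule
  p5 <- p; p5$response_saturation <- 0.5
  times <- c(10, 10.7, 11.4, 12.1)
  res5 <- apply_stim_effects(night, times, volumes = v, params = p5)
  brute <- rep(1, length(night$eeg))
  k <- 0; train_end <- -1
  for (tt in times) {
    s <- floor(tt * 250) + 1
    k <- if (s <= train_end) k + 1 else 1
    e <- s + findInterval(night$phase[s] + 4 * 2 * pi, night$phase[s:length(brute)])
    brute[s:e] <- brute[s:e] * (1 + 0.2 * vw * 0.5^(k - 1))
    train_end <- max(train_end, e)
  }
  expect_equal(res5$multiplier, brute, tolerance = 1e-12)
  marg <- 0.2 * vw * 0.5^(0:3)
  expect_true(all(diff(marg) < 0))

  expect_error(apply_stim_effects(night, times = c(5, 3)), "non-decreasing")
})

test_that("cohort designs count, separate classes, and reproduce exactly", {
  co <- generate_cohort(4, c(strong = 2, weak = 2), nights_per_condition = 2,
                        conditions = c("verum", "sham"),
                        approaches = c("windowed", "continuous"), seed = 3)
  expect_equal(nrow(co$nights), 32)  # 4 x 2 x 2 x 2
  expect_true(min(co$subjects$g[co$subjects$class == "strong"]) >
              max(co$subjects$g[co$subjects$class == "weak"]))
  co2 <- generate_cohort(4, c(strong = 2, weak = 2), nights_per_condition = 2,
                         conditions = c("verum", "sham"),
                         approaches = c("windowed", "continuous"), seed = 3)
  expect_identical(co, co2)
  expect_error(generate_cohort(4, c(strong = 3, weak = 2)), "sum")
})

test_that("tone-marked and unmarked epochs are alike when the gain is zero", {
  # response neutrality: with g = 0, lowSWA of epochs that received tones is
  # statistically indistinguishable from epochs that did not
  fx <- fx_null_run()
  ep <- consecutive_stim_epochs(fx$run, fx$hyp)
  # compare like with like: only epochs lying fully in stimulation-eligible
  # SWS time, where the scheduler (not sleep depth) decides who gets tones
  track <- fx$run$track
  eligible <- vapply(seq_len(nrow(ep)), function(i) {
    secs <- (ep$start_s[i] + 1):(ep$start_s[i] + 6)
    all(secs <= nrow(track)) && all(track$sws[secs] == 1) &&
      all(track$stim_enabled[secs] == 1)
  }, logical(1))
  inc <- ep[ep$included & eligible, ]
  marked <- inc$lowswa[inc$stim_count > 0]
  unmarked <- inc$lowswa[inc$stim_count == 0]
  if (length(marked) > 5 && length(unmarked) > 5) {
    p <- stats::wilcox.test(marked, unmarked)$p.value
    expect_gt(p, 0.01)
  }
  expect_identical(fx$run$eeg, fx$night$eeg)  # signal untouched
})
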