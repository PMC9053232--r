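# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  hit <- get0(name, envir = .fixtures)
  if (!is.null(hit)) return(hit)
  val <- build()
  assign(name, val, envir = .fixtures)
  val
}

# default generator parameters (shared so threshold calibration is cached)
fx_params <- function() fixture("params", function() gen_params())

# a short N3-dominated night with the closed-loop response disabled
fx_null_night <- function() fixture("null_night", function() {
  p <- gen_params(response_gain = 0)
  hyp <- generate_hypnogram(stage_bouts(c("W", "N2", "N3"), c(2, 8, 30)))
  list(params = p, hyp = hyp, night = generate_night(hyp, p, seed = 7L))
})

# the same night run through the engine (verum, windowed)
fx_null_run <- function() fixture("null_run", function() {
  fx <- fx_null_night()
  cfg <- engine_config(fx$params, mode = "verum", approach = "windowed")
  list(cfg = cfg, run = run_night(fx$night, cfg),
       night = fx$night, hyp = fx$hyp)
})

# engine config with fixed dummy thresholds (no calibration needed)
fx_plain_config <- function(...) {
  engine_config(NULL, low_delta_min = 1, high_delta_min = 1,
                nrem_beta_max = 1e9, sws_delta_min = 1, beta_veto_max = 1e9,
                ...)
}

# circular helpers for phase statistics
circ_mean_deg <- function(deg) {
  (atan2(mean(sin(deg * pi / 180)), mean(cos(deg * pi / 180))) * 180 / pi) %% 360
}
circ_diff_deg <- function(a, b) ((a - b + 180) %% 360) - 180
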