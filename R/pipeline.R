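#' Summarize one simulated or recorded night
#'
#' Runs the offline pipeline over an engine run: epoch selection and lowSWA,
#' baseline lowSWA over the device's 10-min control window, lowSWE, the
#' ON-OFF contrast (windowed nights), sleep architecture, arousal count, and
#' the night QC decision.
#'
#' @param run a `stim_run` from [run_night()].
#' @param night the `psg_night` that produced it.
#' @param config the engine config of the run.
#' @param detect_arousals_offline run the (slower) offline arousal detector?
#' @return list of class `night_summary`.
#' @export
summarize_night <- function(run, night, config = run$config,
                            detect_arousals_offline = FALSE) {
  ep <- consecutive_stim_epochs(run, night$hypnogram, config)
  arch <- sleep_architecture(night$hypnogram)

  baseline_lowswa <- NA_real_
  baseline_pct_n3 <- NA_real_
  if (!is.null(run$baseline_window)) {
    bw <- run$baseline_window
    sel <- ep$start_s >= bw["start"] & ep$start_s + 6 <= bw["end"] & ep$included
    if (any(sel)) baseline_lowswa <- mean(ep$lowswa[sel])
    stages <- stage_track(night$hypnogram, 1)
    bsec <- (floor(bw["start"]) + 1L):min(length(stages), ceiling(bw["end"]))
    baseline_pct_n3 <- 100 * mean(stages[bsec] == 4L)
  }

  contrast <- if (config$approach == "windowed")
    onoff_contrast(run, night$hypnogram, config) else NULL

  # stimulations during detected NREM (device track), all logged events
  track <- run$track
  ev_sec <- pmin(nrow(track), floor(run$log$t_s) + 1L)
  n_stims_nrem <- sum(track$nrem[ev_sec] == 1L)

  qc <- night_qc(run$qc_sec, truncated = isTRUE(run$truncated))

  structure(list(
    baseline_lowswa = baseline_lowswa,
    baseline_pct_n3 = baseline_pct_n3,
    lowswa_gt2 = mean(ep$lowswa[ep$included & ep$gt2]),
    lowswe = compute_low_swe(ep),
    n_stims_nrem = n_stims_nrem,
    n_tones = sum(run$log$kind == "tone"),
    mean_volume = if (nrow(run$log)) mean(run$log$volume_db) else NA_real_,
    onoff = contrast,
    diff_gt2 = if (!is.null(contrast) && !is.null(contrast$gt2))
      contrast$gt2$diff else NA_real_,
    architecture = arch,
    arousal_count = if (detect_arousals_offline)
      nrow(detect_arousals(run$eeg, night$hypnogram, config$fs)) else NA_integer_,
    qc_excluded = !qc$keep, qc_reason = qc$reason,
    epochs = ep), class = "night_summary")
}

#' @export
print.night_summary <- function(x, ...) {
  cat(sprintf("<night_summary> baseline lowSWA %.1f uV^2; lowSWE %.0f; %d NREM stims; mean vol %.1f dB\n",
              x$baseline_lowswa, x$lowswe, x$n_stims_nrem, x$mean_volume))
  if (!is.na(x$diff_gt2))
    cat(sprintf("  ON-OFF lowSWA diff (>2 stim): %.2f uV^2\n", x$diff_gt2))
  invisible(x)
}

#' Simulate and analyze a whole cohort
#'
#' Realizes every night of a [generate_cohort()] design: generates the
#' synthetic polysomnography, runs the closed-loop engine in the night's
#' condition and approach, and summarizes it. Fully deterministic given the
#' cohort (whose design carries per-night seeds).
#'
#' @param cohort a `cohort`.
#' @param template night-design template passed to [generate_hypnogram()].
#' @param config_args extra arguments for [engine_config()] applied to every
#'   night (mode/approach come from the design).
#' @param progress print one line per night?
#' @return data.frame, one row per night, with design columns plus
#'   `baseline_lowswa`, `baseline_pct_n3`, `diff_gt2`, `lowswa_gt2`,
#'   `lowswe`, `n_stims_nrem`, `n_tones`, `mean_volume`, `pct_n3`,
#'   `qc_excluded`. The per-night `night_summary` objects are attached as
#'   the `summaries` attribute.
#' @export
run_cohort <- function(cohort, template = default_night_template(90),
                       config_args = list(), progress = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- vector("list", nrow(cohort$nights))
  sums <- vector("list", nrow(cohort$nights))
  for (i in seq_len(nrow(cohort$nights))) {
    d <- cohort$nights[i, ]
    params <- subject_params(cohort, d$subject)
    hyp <- generate_hypnogram(template, seed = d$seed)
    night <- generate_night(hyp, params, seed = d$seed)
    cfg <- do.call(engine_config,
                   c(list(gen_params = params, mode = d$condition,
                          approach = d$approach), config_args))
    run <- run_night(night, cfg)
    s <- summarize_night(run, night, cfg)
    sums[[i]] <- s
    rows[[i]] <- data.frame(
      d, baseline_lowswa = s$baseline_lowswa,
      baseline_pct_n3 = s$baseline_pct_n3,
      diff_gt2 = s$diff_gt2, lowswa_gt2 = s$lowswa_gt2, lowswe = s$lowswe,
      n_stims_nrem = s$n_stims_nrem, n_tones = s$n_tones,
      mean_volume = s$mean_volume,
      pct_n3 = s$architecture$pct[["N3"]],
      qc_excluded = s$qc_excluded, stringsAsFactors = FALSE)
    if (progress)
      cat(sprintf("%s %s/%s night %d: diff_gt2 = %.2f\n", d$subject,
                  d$condition, d$approach, d$night, s$diff_gt2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summaries") <- sums
  out
}

#' Long-format export of cohort window statistics
#'
#' Tidy per-night per-bin table (subject, condition, approach, night, bin,
#' mean ON, mean OFF, difference) for external mixed-model fitting.
#'
#' @param cohort_results result of [run_cohort()].
#' @return data.frame in long format.
#' @export
cohort_long_table <- function(cohort_results) {
  sums <- attr(cohort_results, "summaries")
  out <- list()
  for (i in seq_len(nrow(cohort_results))) {
    s <- sums[[i]]
    if (is.null(s$onoff)) next
    b <- rbind(s$onoff$bins, s$onoff$gt2)
    out[[length(out) + 1L]] <- data.frame(
      cohort_results[i, c("subject", "condition", "approach", "night")],
      b, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
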