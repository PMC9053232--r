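#' Signal file I/O
#'
#' Signals are stored as a documented plain-text CSV: comment header lines
#' `# fs=<Hz>` and `# units=uV`, then one `value` column with one sample per
#' row. Values are written with enough digits to round-trip within the
#' 16-bit quantization of a +/-500 uV physical range (step ~0.0153 uV), the
#' range the original device format would use.
#'
#' @param x samples, uV.
#' @param fs sampling rate, Hz.
#' @param path file path.
#' @return `read_signal`: list of class `signal_record` with `samples`,
#'   `fs`, `units`, `qc` (non-finite / out-of-range mask), `truncated`.
#' @export
write_signal <- function(x, fs, path) {
  q <- 1000 / 2^16  # +/-500 uV over 16 bits
  xq <- round(as.numeric(x) / q) * q
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%g", fs), "# units=uV", "value"), con)
  writeLines(formatC(xq, format = "g", digits = 9), con)
  invisible(path)
}

#' @rdname write_signal
#' @param expect_fs if given, reject a file whose sampling rate differs.
#' @export
read_signal <- function(path, expect_fs = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("fs=", hdr, value = TRUE)
  if (length(fs_line) == 0) stop("signal file missing '# fs=' header: ", path)
  fs <- as.numeric(sub(".*fs=", "", fs_line[1]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0 || body[1] != "value")
    stop("signal file missing 'value' column header: ", path)
  vals <- suppressWarnings(as.numeric(body[-1]))
  bad_cell <- which(is.na(vals) & body[-1] != "NA" & body[-1] != "NaN")
  if (length(bad_cell) > 0)
    stop(sprintf("non-numeric sample at row %d of %s", bad_cell[1], path))
  if (!is.null(expect_fs) && fs != expect_fs)
    stop(sprintf("sampling rate mismatch: file %g Hz, expected %g Hz",
                 fs, expect_fs))
  qc <- !is.finite(vals) | abs(vals) > 1000
  structure(list(samples = vals, fs = fs, units = "uV", qc = qc,
                 truncated = FALSE),
            class = "signal_record")
}

#' Hypnogram file I/O
#'
#' CSV with columns `epoch_index`, `onset_s`, `stage` (20-s AASM epochs).
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  write.csv(as.data.frame(hyp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "onset_s", "stage")
  if (!all(need %in% names(df)))
    stop("hypnogram file must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$epoch_index), ]
  if (nrow(df) > 1) {
    el <- diff(df$onset_s)
    if (length(unique(el)) != 1L)
      stop("hypnogram epochs are not contiguous")
  }
  el <- if (nrow(df) > 1) df$onset_s[2] - df$onset_s[1] else 20
  hypnogram(df$stage, epoch_length = as.numeric(el),
            start_time = as.numeric(df$onset_s[1]))
}

#' Stimulation-log file I/O
#'
#' TSV with columns `t_s`, `kind`, `volume_db`, `phase_est_deg`,
#' `window_label`, `window_index`. Reading enforces the log invariants:
#' strictly increasing event times at least the refractory interval apart,
#' and known kind/window labels.
#'
#' @param log a StimLog data.frame (e.g. `run$log`).
#' @param path file path.
#' @export
write_stimlog <- function(log, path) {
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimlog
#' @param refractory minimum inter-event interval to enforce, s.
#' @export
read_stimlog <- function(path, refractory = 0.5) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("t_s", "kind", "volume_db", "phase_est_deg", "window_label",
            "window_index")
  if (!all(need %in% names(df)))
    stop("stim log must have columns ", paste(need, collapse = ", "))
  if (nrow(df) > 1) {
    dt <- diff(df$t_s)
    if (any(dt <= 0)) stop("stim log event times must be strictly increasing")
    if (any(dt < refractory - 1e-9))
      stop(sprintf("stim log violates the %.3g s refractory invariant at t = %.3f s",
                   refractory, df$t_s[which(dt < refractory - 1e-9)[1] + 1]))
  }
  bad <- setdiff(unique(df$kind), c("tone", "trigger"))
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "))
  df
}

#' Device-track and summary I/O
#'
#' The per-second device track is a CSV (`second`, `nrem`, `sws`,
#' `beta_veto`, `stim_enabled`, `window`); night summaries and manifests are
#' JSON.
#'
#' @param track per-second device-track data.frame.
#' @param path file path.
#' @export
write_track <- function(track, path) {
  write.csv(track, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read.csv(path)
  need <- c("second", "nrem", "sws", "beta_veto", "stim_enabled", "window")
  if (!all(need %in% names(df)))
    stop("device track must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname write_track
#' @param x any list-like summary object.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run configuration I/O (YAML)
#'
#' Round-trips the full run configuration (engine config, generator
#' parameters, analysis settings, seeds) through YAML.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(config, unclass), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
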