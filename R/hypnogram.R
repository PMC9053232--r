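#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of sleep-stage labels scored on fixed
#' 20-s epochs, using the five AASM stages `W`, `N1`, `N2`, `N3`, `R`.
#'
#' @param stages character vector of stage labels, one per 20-s epoch.
#' @param epoch_length epoch length in seconds (fixed at 20 by scoring
#'   convention; other values are allowed for toy examples).
#' @param start_time recording time of the first epoch, seconds.
#' @return An object of class `hypnogram`: a character vector of stages with
#'   `epoch_length` and `start_time` attributes.
#' @export
hypnogram <- function(stages, epoch_length = 20, start_time = 0) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad) > 0L)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         " (expected W, N1, N2, N3, R)")
  stopifnot(epoch_length > 0, start_time >= 0)
  structure(stages, class = "hypnogram",
            epoch_length = epoch_length, start_time = start_time)
}

#' @export
print.hypnogram <- function(x, ...) {
  el <- attr(x, "epoch_length")
  cat(sprintf("<hypnogram> %d epochs x %gs = %.1f min\n",
              length(x), el, length(x) * el / 60))
  tab <- table(factor(unclass(x), levels = STAGE_LEVELS))
  cat(paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.hypnogram <- function(x, ...) {
  el <- attr(x, "epoch_length")
  data.frame(epoch_index = seq_along(x) - 1L,
             onset_s = attr(x, "start_time") + (seq_along(x) - 1L) * el,
             stage = unclass(x), stringsAsFactors = FALSE)
}

#' Total duration of a hypnogram in seconds
#' @param x a `hypnogram`.
#' @return duration in seconds.
#' @export
hypnogram_duration <- function(x) {
  stopifnot(inherits(x, "hypnogram"))
  length(x) * attr(x, "epoch_length")
}

#' Night-design templates for hypnogram generation
#'
#' Two template forms are supported:
#' * a deterministic bout list: `data.frame(stage, minutes)` (or a list of
#'   `(stage, minutes)` pairs) laying out stage bouts in order;
#' * a stochastic first-order Markov cycle model created with
#'   [markov_template()].
#'
#' @param template see Details.
#' @param seed integer seed; generation is a pure function of
#'   `(template, seed)`.
#' @return a [hypnogram()].
#' @examples
#' h <- generate_hypnogram(stage_bouts(c("W", "N2", "N3"), c(5, 15, 40)))
#' table(unclass(h))
#' @export
generate_hypnogram <- function(template, seed = 1L) {
  if (inherits(template, "markov_template")) {
    return(with_seed(seed, markov_hypnogram(template)))
  }
  if (is.list(template) && !is.data.frame(template))
    template <- do.call(rbind, lapply(template, function(b)
      data.frame(stage = b[[1]], minutes = as.numeric(b[[2]]))))
  stopifnot(is.data.frame(template), all(c("stage", "minutes") %in% names(template)))
  if (any(template$minutes <= 0)) stop("bout durations must be positive")
  epochs_per_bout <- round(template$minutes * 60 / 20)
  if (any(epochs_per_bout == 0)) stop("bout shorter than one 20-s epoch")
  hypnogram(rep(as.character(template$stage), epochs_per_bout))
}

#' @rdname generate_hypnogram
#' @param stages,minutes parallel vectors of stage labels and bout durations.
#' @export
stage_bouts <- function(stages, minutes) {
  data.frame(stage = as.character(stages), minutes = as.numeric(minutes))
}

#' @rdname generate_hypnogram
#' @param transition 5x5 row-stochastic matrix of per-epoch stage transition
#'   probabilities, rows/columns ordered `W,N1,N2,N3,R`.
#' @param init initial stage distribution (defaults to starting awake).
#' @param duration_min total night duration in minutes.
#' @export
markov_template <- function(transition, init = c(1, 0, 0, 0, 0),
                            duration_min = 480) {
  transition <- as.matrix(transition)
  stopifnot(all(dim(transition) == c(5L, 5L)),
            all(transition >= 0),
            max(abs(rowSums(transition) - 1)) < 1e-8,
            length(init) == 5L, all(init >= 0), abs(sum(init) - 1) < 1e-8,
            duration_min > 0)
  dimnames(transition) <- list(STAGE_LEVELS, STAGE_LEVELS)
  structure(list(transition = transition, init = init,
                 n_epochs = max(1L, round(duration_min * 3))),
            class = "markov_template")
}

markov_hypnogram <- function(tmpl) {
  n <- tmpl$n_epochs
  stages <- integer(n)
  stages[1] <- sample.int(5L, 1L, prob = tmpl$init)
  for (i in seq_len(n - 1L))
    stages[i + 1L] <- sample.int(5L, 1L, prob = tmpl$transition[stages[i], ])
  hypnogram(STAGE_LEVELS[stages])
}

#' Default stochastic night model
#'
#' A sticky Markov chain whose bouts emulate an older adult's night at desk
#' scale: wake at lights-off, descent through N1/N2 into N3, periodic REM.
#'
#' @param duration_min night duration, minutes.
#' @return a `markov_template`.
#' @export
default_night_template <- function(duration_min = 480) {
  # rows: from-stage W, N1, N2, N3, R; sticky diagonal, AASM-plausible moves
  P <- rbind(
    W  = c(0.92, 0.08, 0.00, 0.00, 0.00),
    N1 = c(0.05, 0.70, 0.25, 0.00, 0.00),
    N2 = c(0.01, 0.03, 0.88, 0.07, 0.01),
    N3 = c(0.00, 0.00, 0.05, 0.94, 0.01),
    R  = c(0.02, 0.05, 0.05, 0.00, 0.88))
  markov_template(P, init = c(1, 0, 0, 0, 0), duration_min = duration_min)
}

# Per-sample stage codes (1..5 indexing STAGE_LEVELS) for a hypnogram.
stage_track <- function(hyp, fs) {
  codes <- match(unclass(hyp), STAGE_LEVELS)
  rep(codes, each = round(attr(hyp, "epoch_length") * fs))
}
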