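#' @useDynLib somnoloop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft median mad filter rnorm runif rpois rbinom
#'   chisq.test pchisq pt qt qnorm pf lm anova binom.test sd var aggregate
#' @importFrom utils read.csv write.csv read.delim write.table head tail
NULL

STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  codes <- utf8ToInt(key)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a volume in dB to the generator's monotone effectiveness weight:
# linear from [46, 60] dB to [0.8, 1.2].
volume_weight <- function(volume_db) {
  0.8 + 0.4 * (volume_db - 46) / 14
}
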