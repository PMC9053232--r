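#' Classify responders by median split
#'
#' Strong responders are the upper 50% of subjects by mean Verum ON-OFF
#' lowSWA difference (windows with more than 2 stimulations), weak
#' responders the lower 50%. For an odd number of subjects the upper
#' `ceiling(n/2)` are strong; exact ties are broken deterministically by
#' subject id (lexicographic, earlier id wins the higher rank) and flagged.
#'
#' @param diffs named numeric vector: per-subject mean Verum ON-OFF
#'   difference, names are subject ids.
#' @return data.frame with `subject`, `criterion_value`, `label`
#'   (`strong`/`weak`); attribute `ties` flags whether the split crossed
#'   tied values.
#' @export
classify_responders <- function(diffs) {
  if (length(diffs) < 2L) stop("need at least 2 subjects")
  if (is.null(names(diffs)) || anyNA(names(diffs)))
    stop("diffs must be named by subject id")
  if (anyNA(diffs))
    stop("NA criterion value; exclude nights without ON-OFF data before ",
         "averaging (e.g. mean(..., na.rm = TRUE))")
  ord <- order(-diffs, names(diffs))
  n_strong <- ceiling(length(diffs) / 2)
  label <- rep("weak", length(diffs))
  label[ord[seq_len(n_strong)]] <- "strong"
  cut_hi <- diffs[ord[n_strong]]
  ties <- n_strong < length(diffs) && diffs[ord[n_strong + 1L]] == cut_hi
  structure(data.frame(subject = names(diffs), criterion_value = unname(diffs),
                       label = label, stringsAsFactors = FALSE),
            ties = ties)
}

#' Repeated-measures correlation
#'
#' The common intra-individual association between two repeated measures:
#' a shared-slope, subject-specific-intercept ANCOVA. The statistic is
#' `r_rm = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))` with
#' `df = N - k - 1` (N observations, k subjects), a two-sided p-value from
#' the corresponding F test, and a 95% CI via the Fisher z transform with
#' standard error `1/sqrt(df - 1)`.
#'
#' Subjects contributing fewer than 2 observations are dropped with a
#' warning.
#'
#' @param x,y paired measurements.
#' @param subject subject identifier for each observation.
#' @param conf_level confidence level of the CI.
#' @return list of class `rmcorr_result`: `r_rm`, `df`, `p`, `ci`, `slope`,
#'   `n_obs`, `n_subjects`.
#' @export
rm_correlation <- function(x, y, subject, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- factor(subject[ok])
  counts <- table(subject)
  if (any(counts < 2L)) {
    warning("dropping subject(s) with a single observation: ",
            paste(names(counts)[counts < 2L], collapse = ", "))
    keep <- subject %in% names(counts)[counts >= 2L]
    x <- x[keep]; y <- y[keep]; subject <- droplevels(subject[keep])
  }
  k <- nlevels(subject)
  if (k < 2L) stop("need at least 2 subjects with repeated observations")
  fit <- lm(y ~ subject + x)
  an <- anova(fit)  # sequential: subject first, then the common slope
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- length(x) - k - 1L
  slope <- unname(coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  p <- stats::pf(an["x", "F value"], 1, df, lower.tail = FALSE)
  z <- atanh(r)
  se <- 1 / sqrt(df - 1)
  ci <- tanh(z + qnorm(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)) * se)
  structure(list(r_rm = r, df = df, p = p, ci = ci, slope = slope,
                 n_obs = length(x), n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r_rm = %.3f (df = %d), 95%% CI [%.3f, %.3f], p = %.3g\n",
              x$r_rm, x$df, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Cross-validated linear discriminant classification
#'
#' Fits Fisher's LDA in a stratified k-fold cross-validation (one predictor
#' or several), pools held-out predictions into accuracy, sensitivity and
#' specificity, and tests the pooled accuracy against the No Information
#' Rate (the largest class prevalence) with a one-tailed binomial test.
#'
#' @param features numeric vector or matrix/data.frame of predictors, one
#'   row per night.
#' @param labels two-level factor (or coercible); the second level in sorted
#'   order is treated as the positive class for sensitivity.
#' @param folds number of folds.
#' @param seed integer seed for the fold assignment.
#' @param positive which class counts as positive (default `"strong"` when
#'   present, else the last level).
#' @return list of class `lda_cv_result`: `accuracy`, `sensitivity`,
#'   `specificity`, `nir`, `p_binomial`, `confusion`, `folds`.
#' @export
lda_crossval <- function(features, labels, folds = 10, seed = 1L,
                         positive = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes")
  if (nrow(X) < folds) stop("need at least as many observations as folds")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 observations")
  if (is.null(positive))
    positive <- if ("strong" %in% levels(labels)) "strong"
                else levels(labels)[2]
  fold_id <- integer(nrow(X))
  with_seed(seed, {
    for (lv in levels(labels)) {  # stratified: spread each class over folds
      idx <- sample(which(labels == lv))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(labels))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (length(unique(labels[tr])) < 2L)
      stop("a training fold contains one class only; reduce folds")
    fit <- MASS::lda(X[tr, , drop = FALSE], grouping = labels[tr])
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])$class
  }
  correct <- sum(pred == labels)
  acc <- correct / length(labels)
  pos <- labels == positive
  sens <- sum(pred == labels & pos) / sum(pos)
  spec <- sum(pred == labels & !pos) / sum(!pos)
  nir <- max(table(labels)) / length(labels)
  p <- stats::binom.test(correct, length(labels), p = nir,
                         alternative = "greater")$p.value
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 nir = nir, p_binomial = p,
                 confusion = table(predicted = pred, truth = labels),
                 folds = folds),
            class = "lda_cv_result")
}

#' @export
print.lda_cv_result <- function(x, ...) {
  cat(sprintf("LDA %d-fold CV: accuracy %.2f (NIR %.2f, one-tailed binomial p = %.3g)\n",
              x$folds, x$accuracy, x$nir, x$p_binomial))
  cat(sprintf("  sensitivity %.2f, specificity %.2f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Pooled-variance two-sample Student t test
#'
#' Works either from raw per-group values or from published summaries
#' (means, SEMs and group sizes, with per-group SD recovered as
#' `SEM * sqrt(n)`). Returns t, df = n1 + n2 - 2, the CI of the mean
#' difference (group1 - group2), and Cohen's d (mean difference over the
#' pooled SD).
#'
#' @param x,y raw values of the two groups, or `NULL` when summaries are
#'   given.
#' @param means,sems,ns length-2 vectors of group summaries.
#' @param conf_level confidence level.
#' @return list of class `two_t_result`: `t`, `df`, `p`, `ci`, `cohens_d`,
#'   `mean_diff`.
#' @export
two_group_t <- function(x = NULL, y = NULL, means = NULL, sems = NULL,
                        ns = NULL, conf_level = 0.95) {
  if (!is.null(x)) {
    stopifnot(!is.null(y), length(x) >= 2, length(y) >= 2)
    means <- c(mean(x), mean(y))
    ns <- c(length(x), length(y))
    sds <- c(sd(x), sd(y))
  } else {
    stopifnot(length(means) == 2, length(sems) == 2, length(ns) == 2,
              all(ns >= 2))
    sds <- sems * sqrt(ns)
  }
  sp2 <- ((ns[1] - 1) * sds[1]^2 + (ns[2] - 1) * sds[2]^2) / (sum(ns) - 2)
  if (sp2 <= 0) stop("pooled variance is zero")
  se <- sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
  d <- means[1] - means[2]
  tval <- d / se
  df <- sum(ns) - 2
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- d + qt(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2), df) * se
  structure(list(t = tval, df = df, p = p, ci = ci,
                 cohens_d = d / sqrt(sp2), mean_diff = d),
            class = "two_t_result")
}

#' @export
print.two_t_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.2f, p = %.3g, diff = %.2f, 95%% CI [%.2f, %.2f], d = %.2f\n",
              x$df, x$t, x$p, x$mean_diff, x$ci[1], x$ci[2], x$cohens_d))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's statistic without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return list of class `chi2_result`: `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins of the 2x2 table must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = 1L, p = ct$p.value),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-square(1) = %.2f, p = %.3g\n", x$chi2, x$p))
  invisible(x)
}

#' @importFrom stats coef predict
NULL
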