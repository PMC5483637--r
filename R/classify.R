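#' Classification configuration
#'
#' Parameters of the single-predictor classification screen: bootstrap
#' replicates, permutation count, significance level, chance accuracy for a
#' binary decision, and the outlier-filter multipliers (`mad_k` for the
#' robust filter used before classification modelling, `sd_k` for the
#' filter used before simple group comparisons).
#'
#' @param n_boot Stratified bootstrap resamples (default 10000).
#' @param n_perm Label permutations (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param chance Chance accuracy (default 0.50).
#' @param mad_k MAD multiplier for the classification filter (default 3).
#' @param sd_k SD multiplier for the group-comparison filter (default 2).
#' @param seed Integer seed driving all resampling.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(n_boot = 10000L, n_perm = 5000L,
                                  alpha = 0.05, chance = 0.50,
                                  mad_k = 3, sd_k = 2, seed = 1L) {
  stopifnot(n_boot >= 1, n_perm >= 1, alpha > 0, alpha < 1,
            chance > 0, chance < 1, mad_k > 0, sd_k > 0)
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 alpha = alpha, chance = chance, mad_k = mad_k, sd_k = sd_k,
                 seed = as.integer(seed)),
            class = "classification_config")
}

#' Outlier filtering by distance from the group mean
#'
#' Single-pass rule used before simple group comparisons: values at or
#' beyond `k` standard deviations from the group mean are removed, with the
#' mean and (sample) SD computed once from the unfiltered values. A
#' degenerate group (SD = 0) removes nothing.
#'
#' @param x Numeric values of one group.
#' @param k Multiplier (default 2).
#' @return A list with `values` (retained), `removed` and logical `keep`.
#' @export
filter_outliers_sd <- function(x, k = 2) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("group must have at least 3 values")
  s <- sd(x)
  keep <- if (s == 0) rep(TRUE, length(x)) else abs(x - mean(x)) < k * s
  list(values = x[keep], removed = x[!keep], keep = keep)
}

#' Outlier filtering by distance from the group median
#'
#' Single-pass robust rule used before classification modelling: values at
#' or beyond `k` scaled MADs (median absolute deviation from the median,
#' consistency constant 1.4826) from the group median are removed. When the
#' MAD is zero, any value differing from the median is removed (the
#' majority defines the distribution).
#'
#' @param x Numeric values of one group.
#' @param k Multiplier (default 3).
#' @param scale Consistency constant (default 1.4826).
#' @return A list with `values`, `removed` and logical `keep`.
#' @export
filter_outliers_mad <- function(x, k = 3, scale = 1.4826) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("group must have at least 3 values")
  med <- median(x)
  m <- mad(x, constant = scale)
  keep <- if (m == 0) x == med else abs(x - med) < k * m
  list(values = x[keep], removed = x[!keep], keep = keep)
}

as_binary_labels <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  f <- factor(y)
  if (nlevels(f) != 2L) stop("labels must have exactly two levels")
  if (is.null(positive)) {
    positive <- if ("MS" %in% levels(f)) "MS" else levels(f)[2L]
  }
  as.integer(f == positive)
}

#' Single-predictor logistic classifier
#'
#' Maximum-likelihood logistic regression of a binary label on one
#' predictor. Complete separation is detected and replaced by the
#' deterministic midpoint-threshold rule (the decision boundary, and hence
#' every accuracy statistic, is all that matters; the unbounded MLE is
#' not needed). Ties at predicted probability 0.5 go to the positive (MS)
#' class.
#'
#' @param x Numeric predictor.
#' @param y Binary labels: logical, 0/1, or a two-level factor/character
#'   (level `"MS"`, else the second level, is the positive class).
#' @return A list of class `logistic_fit` with `intercept`, `slope`,
#'   `separated`, `boundary`, `direction`.
#' @export
fit_logistic <- function(x, y) {
  y <- as_binary_labels(y)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  f <- cpp_fit_logistic(as.numeric(x), y)
  structure(list(intercept = unname(f["intercept"]),
                 slope = unname(f["slope"]),
                 separated = f["separated"] > 0,
                 boundary = unname(f["boundary"]),
                 direction = as.integer(f["direction"])),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$separated) {
    cat(sprintf("Logistic fit: complete separation; boundary %.4g (direction %+d)\n",
                x$boundary, x$direction))
  } else {
    cat(sprintf("Logistic fit: intercept %.4g, slope %.4g\n",
                x$intercept, x$slope))
  }
  invisible(x)
}

#' Training (within-sample) classification accuracy
#'
#' Proportion of correct classification outcomes over all outcomes when the
#' model fitted on `(x, y)` classifies its own training points at
#' probability threshold 0.5.
#'
#' @inheritParams fit_logistic
#' @return Accuracy in `[0, 1]`.
#' @export
within_accuracy <- function(x, y) {
  y <- as_binary_labels(y)
  cpp_within_accuracy(as.numeric(x), y)
}

#' Leave-one-out cross-validated accuracy
#'
#' Fits N models, each on N-1 participants, and scores the prediction of
#' the held-out participant; the N fold outcomes are averaged. A training
#' fold containing a single class predicts that class.
#'
#' @inheritParams fit_logistic
#' @return Out-of-sample accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(x, y) {
  y <- as_binary_labels(y)
  if (length(x) < 3L) stop("LOOCV needs at least 3 observations")
  cpp_loocv(as.numeric(x), y)
}

stratified_resample_indices <- function(y, n_boot) {
  groups <- split(seq_along(y), y)
  idx <- matrix(0L, length(y), n_boot)
  pos <- 1L
  for (g in groups) {
    ng <- length(g)
    draws <- matrix(g[sample.int(ng, ng * n_boot, replace = TRUE)], ng, n_boot)
    idx[pos:(pos + ng - 1L), ] <- draws
    pos <- pos + ng
  }
  idx
}

bca_interval <- function(stats, observed, jack, conf) {
  B <- length(stats)
  if (all(stats == stats[1L])) {
    return(list(lcl = stats[1L], ucl = stats[1L], z0 = 0, accel = 0,
                degenerate = TRUE))
  }
  # bias correction from the bootstrap CDF at the observed statistic;
  # ties counted half because accuracy is heavily discrete
  p0 <- (sum(stats < observed) + 0.5 * sum(stats == observed)) / B
  p0 <- min(max(p0, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(p0)
  # acceleration from the leave-one-out jackknife
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zlo <- qnorm((1 - conf) / 2)
  zhi <- -zlo
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  s <- sort(stats)
  pick <- function(p) s[min(B, max(1L, ceiling(p * B)))]
  list(lcl = pick(adj(zlo)), ucl = pick(adj(zhi)), z0 = z0, accel = a,
       degenerate = FALSE)
}

#' Stratified BCa bootstrap interval for within-sample accuracy
#'
#' Draws `n_boot` stratified resamples (within-group sampling with
#' replacement, preserving each group's n and hence the original
#' patient/control composition), refits the classifier on each resample and
#' scores it on that resample. The bias-corrected and accelerated interval
#' uses the bootstrap CDF at the observed accuracy for the bias term (ties
#' counted half) and the leave-one-out jackknife for acceleration; interval
#' endpoints are order statistics of the bootstrap distribution. The
#' predictor is significant when the interval excludes all values at or
#' below chance (lower limit > `chance`).
#'
#' @inheritParams fit_logistic
#' @param n_boot Number of resamples.
#' @param conf Confidence level (default 0.95).
#' @param chance Chance accuracy (default 0.50).
#' @param seed Optional integer seed.
#' @return A list of class `bca_accuracy`: `observed`, `lcl`, `ucl`,
#'   `significant`, `z0`, `accel`, `n_boot`.
#' @export
bca_bootstrap_accuracy <- function(x, y, n_boot = 10000L, conf = 0.95,
                                   chance = 0.50, seed = NULL) {
  y <- as_binary_labels(y)
  x <- as.numeric(x)
  if (min(table(y)) < 2L) stop("need at least 2 observations per group")
  if (!is.null(seed)) set.seed(seed)
  observed <- cpp_within_accuracy(x, y)
  idx <- stratified_resample_indices(y, n_boot)
  stats <- cpp_boot_accuracy(x, y, idx)
  jack <- vapply(seq_along(x),
                 function(i) cpp_within_accuracy(x[-i], y[-i]),
                 numeric(1))
  ci <- bca_interval(stats, observed, jack, conf)
  structure(list(observed = observed, lcl = ci$lcl, ucl = ci$ucl,
                 significant = ci$lcl > chance,
                 z0 = ci$z0, accel = ci$accel,
                 degenerate = ci$degenerate, n_boot = n_boot),
            class = "bca_accuracy")
}

#' @export
print.bca_accuracy <- function(x, ...) {
  cat(sprintf("Within-sample accuracy %.3f, BCa 95%% CI [%.3f, %.3f]%s (B = %d)\n",
              x$observed, x$lcl, x$ucl,
              if (x$significant) ", above chance" else "", x$n_boot))
  invisible(x)
}

#' Permutation p-value for LOOCV accuracy
#'
#' Builds the null distribution by permuting the group labels `n_perm`
#' times (uniformly over label orderings) and recomputing the LOOCV
#' accuracy for each permutation. The p-value uses the add-one correction
#' `p = (#\{acc_perm >= acc_obs\} + 1) / (n_perm + 1)`; setting
#' `correction = FALSE` gives the raw proportion of permuted accuracies at
#' or above the observed one, and `strict = TRUE` counts only strictly
#' greater permuted accuracies.
#'
#' @inheritParams fit_logistic
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param correction Apply the add-one correction (default TRUE).
#' @param strict Count only strictly greater accuracies (default FALSE).
#' @return A list of class `perm_test`: `observed`, `p`, `n_perm`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 5000L, seed = NULL,
                               correction = TRUE, strict = FALSE) {
  y <- as_binary_labels(y)
  x <- as.numeric(x)
  if (!is.null(seed)) set.seed(seed)
  observed <- cpp_loocv(x, y)
  ymat <- vapply(seq_len(n_perm), function(k) sample(y), integer(length(y)))
  accs <- cpp_loocv_many(x, ymat)
  hits <- if (strict) sum(accs > observed) else sum(accs >= observed)
  p <- if (correction) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed = observed, p = p, n_perm = n_perm,
                 null_accuracies = accs),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("LOOCV accuracy %.3f, permutation p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1,
#' order-preserving with the input).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite (fractional) degrees of
#' freedom and a two-sided p-value; the sign of t follows the sign of
#' `mean(x_a) - mean(x_b)`.
#'
#' @param x_a,x_b Numeric values of the two groups (n >= 2 each).
#' @return A list of class `group_comparison`: `t`, `df`, `p`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t <- function(x_a, x_b) {
  stopifnot(length(x_a) >= 2L, length(x_b) >= 2L)
  if (sd(x_a) == 0 && sd(x_b) == 0) {
    stop("both groups have zero variance: test undefined")
  }
  ht <- t.test(x_a, x_b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(x_a), mean_b = mean(x_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Cohen's d with pooled SD
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled`, pooling the
#' two group variances with n-1 weights.
#'
#' @inheritParams welch_t
#' @return Effect size d.
#' @export
cohens_d <- function(x_a, x_b) {
  na <- length(x_a); nb <- length(x_b)
  stopifnot(na >= 2L, nb >= 2L)
  sp <- sqrt(((na - 1) * var(x_a) + (nb - 1) * var(x_b)) / (na + nb - 2))
  if (sp == 0) stop("pooled SD is zero: effect size undefined")
  (mean(x_a) - mean(x_b)) / sp
}
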