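test_that("SD outlier filter removes only far points, single pass", {
  # 20 zeros and one 10: mean 0.476, sample SD 2.18 -> |10 - mean| >= 2 SD
  x <- c(rep(0, 20), 10)
  f <- filter_outliers_sd(x)
  expect_equal(f$removed, 10)
  expect_equal(length(f$values), 20L)
  # a lone moderate point inside 2 SD survives
  expect_equal(filter_outliers_sd(c(1, 1, 1, 1, 9))$removed, numeric(0))
  expect_equal(filter_outliers_sd(rep(3, 5))$values, rep(3, 5))
  expect_error(filter_outliers_sd(c(1, 2)), "at least 3")
})

test_that("MAD outlier filter matches the hand-computed rule", {
  # median 2.5, MAD (scaled) 1.4826, cutoff 4.4478: only 100 removed
  f <- filter_outliers_mad(c(1, 2, 3, 100))
  expect_equal(f$removed, 100)
  expect_equal(f$values, c(1, 2, 3))
  # 1..5: max deviation 2 < cutoff 4.45, unchanged
  expect_equal(filter_outliers_mad(1:5)$values, 1:5)
  expect_equal(filter_outliers_mad(rep(7, 4))$values, rep(7, 4))
  # zero MAD: everything off the median is removed
  f0 <- filter_outliers_mad(c(5, 5, 5, 5, 8))
  expect_equal(f0$removed, 8)
})

test_that("logistic fit agrees with an independent ML implementation", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0L, 1L, 0L, 1L, 0L, 1L)
  f <- fit_logistic(x, y)
  expect_false(f$separated)
  ref <- suppressWarnings(glm(y ~ x, family = binomial()))
  expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-5)
  # a larger overlapping fixture
  set.seed(14)
  x2 <- c(rnorm(12, 0), rnorm(12, 1))
  y2 <- rep(c(0L, 1L), each = 12)
  f2 <- fit_logistic(x2, y2)
  ref2 <- glm(y2 ~ x2, family = binomial())
  expect_equal(f2$intercept, unname(coef(ref2)[1]), tolerance = 1e-5)
  expect_equal(f2$slope, unname(coef(ref2)[2]), tolerance = 1e-5)
  expect_error(fit_logistic(1:4, c(1L, 1L, 1L, 1L)), "both classes")
})

test_that("complete separation falls back to the midpoint threshold", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  f <- fit_logistic(x, y)
  expect_true(f$separated)
  expect_equal(f$boundary, 6.5)
  expect_equal(f$direction, 1L)
  expect_equal(within_accuracy(x, y), 1.0)
})

test_that("within-sample accuracy has its closed forms", {
  y <- study_labels()            # 10 MS, 13 HC
  # constant predictor: intercept-only model predicts the majority class
  expect_equal(within_accuracy(rep(3, 23), y), 13 / 23)
  f <- fit_logistic(rep(3, 23), y)
  expect_equal(f$slope, 0)
  expect_equal(plogis(f$intercept), 10 / 23, tolerance = 1e-10)
})

test_that("LOOCV accuracy matches closed forms and hand enumeration", {
  y <- study_labels()
  expect_equal(loocv_accuracy(rep(1, 23), y), 13 / 23)
  expect_equal(loocv_accuracy(separated_predictor(), y), 1.0)
  # 3-point fixture, folds enumerated by hand:
  # fold 1 trains on two HC -> predicts HC, truth MS (wrong);
  # fold 2 boundary 2 with ties to MS -> predicts MS, truth HC (wrong);
  # fold 3 boundary 1.5, x=3 above -> predicts HC, truth HC (right).
  expect_equal(loocv_accuracy(c(1, 2, 3), c(1L, 0L, 0L)), 1 / 3)
})

test_that("BCa machinery reduces to percentile under zero correction", {
  stats <- (1:100) / 100
  jack <- c(1, 2, 3, 4, 5)           # symmetric: acceleration 0
  ci <- calfmri:::bca_interval(stats, observed = 0.505, jack = jack,
                               conf = 0.95)
  expect_equal(ci$z0, 0)
  expect_equal(ci$accel, 0)
  expect_equal(ci$lcl, stats[3])     # order statistic at ceiling(0.025 B)
  expect_equal(ci$ucl, stats[98])
  # the interval contains the bootstrap median in this regime
  expect_true(ci$lcl <= median(stats) && median(stats) <= ci$ucl)
  # all-identical bootstrap statistics give a degenerate interval
  ci2 <- calfmri:::bca_interval(rep(0.7, 50), 0.7, jack, 0.95)
  expect_equal(c(ci2$lcl, ci2$ucl), c(0.7, 0.7))
})

test_that("stratified resampling preserves group sizes", {
  y <- study_labels()
  set.seed(2)
  idx <- calfmri:::stratified_resample_indices(y, 200)
  for (b in c(1, 57, 200)) {
    expect_equal(sum(y[idx[, b]] == 1), 10)
    expect_equal(sum(y[idx[, b]] == 0), 13)
  }
})

test_that("bootstrap interval matches exhaustive enumeration on n = 4", {
  x <- c(1, 3, 2, 4)
  y <- c(1L, 1L, 0L, 0L)
  obs <- within_accuracy(x, y)
  # exhaustive oracle over all 2^2 * 2^2 ordered stratified resamples
  ms <- which(y == 1); hc <- which(y == 0)
  combos <- expand.grid(a = ms, b = ms, c = hc, d = hc)
  stats_ex <- apply(combos, 1, function(idx)
    within_accuracy(x[idx], y[idx]))
  p0 <- (sum(stats_ex < obs) + 0.5 * sum(stats_ex == obs)) / 16
  z0 <- qnorm(p0)
  jack <- vapply(1:4, function(i) within_accuracy(x[-i], y[-i]), numeric(1))
  jm <- mean(jack)
  a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  s <- sort(stats_ex)
  lcl_ex <- s[max(1, ceiling(adj(qnorm(0.025)) * 16))]
  ucl_ex <- s[min(16, ceiling(adj(qnorm(0.975)) * 16))]
  mc <- bca_bootstrap_accuracy(x, y, n_boot = 20000, seed = 2)
  expect_equal(mc$lcl, lcl_ex)
  expect_equal(mc$ucl, ucl_ex)
  expect_equal(mc$z0, z0, tolerance = 0.05)
})

test_that("degenerate perfect separation gives a [1, 1] interval", {
  x <- c(1, 2, 30, 40, 3, 4, 50, 60)
  y <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  b <- bca_bootstrap_accuracy(x, y, n_boot = 500, seed = 3)
  expect_equal(c(b$lcl, b$ucl), c(1, 1))
  expect_true(b$significant)
})

test_that("permutation p-value matches exhaustive labelings on n = 6", {
  x <- c(1.2, 3.1, 2.0, 4.5, 2.8, 5.0)
  y <- c(0L, 1L, 0L, 1L, 0L, 1L)
  obs <- loocv_accuracy(x, y)
  labs <- combn(6, 3)
  acc_ex <- apply(labs, 2, function(ii) {
    yy <- rep(0L, 6); yy[ii] <- 1L
    loocv_accuracy(x, yy)
  })
  p_ex <- mean(acc_ex >= obs)
  n_perm <- 2000
  pt <- permutation_pvalue(x, y, n_perm = n_perm, seed = 1)
  raw <- sum(pt$null_accuracies >= obs) / n_perm
  se <- sqrt(p_ex * (1 - p_ex) / n_perm)
  expect_lt(abs(raw - p_ex), 3 * se)
})

test_that("permutation p-value hits its floor for strong separation", {
  x <- separated_predictor()
  y <- study_labels()
  pt <- permutation_pvalue(x, y, n_perm = 499, seed = 9)
  expect_equal(pt$observed, 1.0)
  expect_equal(pt$p, 1 / 500)
  # the raw (uncorrected) variant reports the plain proportion
  pt2 <- permutation_pvalue(x, y, n_perm = 499, seed = 9, correction = FALSE)
  expect_equal(pt2$p, 0)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 / 0.75, 0.5))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  p <- c(0.003, 0.04, 0.7, 0.011)
  expect_true(all(benjamini_hochberg(p) >= p))
})

test_that("Welch test and Cohen's d match hand formulas", {
  w <- welch_t(c(1, 2, 3), c(5, 6, 7))
  expect_equal(w$t, -4.898979485566, tolerance = 1e-9)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.008049893101, tolerance = 1e-8)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  flipped <- welch_t(c(5, 6, 7), c(1, 2, 3))
  expect_equal(flipped$t, -w$t)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
  expect_equal(cohens_d(c(1, 2, 3), c(5, 6, 7)), -4)
  expect_equal(cohens_d(c(2, 4), c(2, 4)), 0)
  expect_error(cohens_d(c(0, 0, 0), c(1, 1, 1)), "pooled SD")
})
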