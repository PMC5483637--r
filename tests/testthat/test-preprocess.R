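test_that("despike replaces isolated spikes and leaves clean series alone", {
  expect_identical(despike(rep(5, 10)), rep(5, 10))
  # classic single spike: detected against the running reference and
  # replaced by the mean of its neighbours
  expect_equal(despike(c(100, 100, 500, 100, 100)), rep(100, 5))
  # bounded noise with no point beyond the threshold: output identical
  set.seed(42)
  x <- 100 + sin(1:80 / 5) + runif(80, -0.5, 0.5)
  expect_identical(despike(x), x)
  # matrix form agrees with the vector form, column by column; the spike
  # is pulled back to the local level and clean columns are untouched
  set.seed(3)
  X <- matrix(rnorm(200, 100, 1), 50, 4)
  X[10, 2] <- 200
  D <- despike(X)
  for (j in 1:4) expect_equal(D[, j], despike(X[, j]))
  expect_lt(abs(D[10, 2] - 100), 3)
  expect_identical(D[, c(1, 3, 4)], X[, c(1, 3, 4)])
})

test_that("surround subtraction recovers control-minus-label", {
  # constant control c = 10, label l = 8 (label first): difference is 2
  expect_equal(surround_subtract(c(8, 10, 8, 10, 8, 10), TRUE), rep(2, 6))
  expect_equal(surround_subtract(c(10, 8, 10, 8, 10, 8), FALSE), rep(2, 6))
  # zero perfusion: identical conditions difference to zero
  expect_equal(surround_subtract(rep(7, 8), TRUE), rep(0, 8))
  # a shared linear drift cancels at interior points
  drift <- 0.5 * (1:12)
  x <- drift + ifelse((1:12) %% 2 == 0, 3, 0)  # controls offset by 3
  out <- surround_subtract(x, label_first = TRUE)
  expect_equal(out[2:11], rep(3, 10))
  expect_error(surround_subtract(c(1, 2), TRUE), "3 volumes")
})

test_that("pair averaging removes alternation and preserves shape", {
  expect_equal(bold_pair_average(rep(4, 6)), rep(4, 6))
  alt <- rep(c(10, 20), 5)
  expect_equal(bold_pair_average(alt)[1:9], rep(15, 9))
  # ramp maps to the midpoint ramp, last volume carried
  expect_equal(bold_pair_average(as.numeric(1:6)), c(1.5, 2.5, 3.5, 4.5, 5.5, 6))
  arr <- array(rnorm(2 * 2 * 2 * 5), c(2, 2, 2, 5))
  out <- bold_pair_average(arr)
  expect_equal(dim(out), dim(arr))
  expect_equal(out[1, 1, 1, ], bold_pair_average(arr[1, 1, 1, ]))
})

test_that("gaussian smoothing is normalised and degenerates to identity", {
  v <- array(rnorm(12 * 12 * 9), c(12, 12, 9))
  expect_identical(smooth_gaussian(v, fwhm_mm = 0), v)
  const <- array(3, c(8, 8, 4))
  expect_equal(smooth_gaussian(const, 8, c(3.44, 3.44, 5)), const,
               tolerance = 1e-12)
  # a delta away from the edges spreads into a kernel of unit mass
  delta <- array(0, c(18, 18, 13)); delta[9, 9, 7] <- 1
  sm <- smooth_gaussian(delta, 8, c(3.44, 3.44, 5))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("high-pass filter meets its attenuation contract", {
  tr <- 4; n <- 150
  t <- (seq_len(n) - 1) * tr
  amp_at <- function(x, f) {
    fit <- lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  slow <- sin(2 * pi * 0.001 * t)
  fast <- sin(2 * pi * 0.02 * t)
  expect_lt(amp_at(highpass(slow, 0.0039, tr), 0.001),
            amp_at(slow, 0.001) / 10)
  expect_gt(amp_at(highpass(fast, 0.0039, tr), 0.02),
            0.95 * amp_at(fast, 0.02))
  expect_equal(highpass(rep(2, n), 0.0039, tr), rep(2, n), tolerance = 1e-10)
  # the series mean (baseline level) is preserved under filtering
  x <- 100 + slow
  expect_equal(mean(highpass(x, 0.0039, tr)), mean(x), tolerance = 1e-9)
  expect_error(highpass(slow, 0.2, tr), "Nyquist")
})

test_that("boxcar GLM returns exact percent change on noiseless series", {
  des <- task_design(n_blocks = 2, block_s = 40,
                     rest_choices_s = 40, tr = 4, seed = 1)
  n <- des$total_duration / 4
  box <- boxcar_regressor(des, n, 4)
  y <- 100 + 2 * box
  fit <- glm_percent_change(y, des, tr = 4)
  expect_equal(fit$percent_change, 2.0, tolerance = 1e-10)
  expect_gt(fit$t, 1e6)
  # constant series: zero effect, t guarded to 0
  fit0 <- glm_percent_change(rep(100, n), des, tr = 4)
  expect_equal(fit0$percent_change, 0)
  expect_equal(fit0$t, 0)
  expect_error(glm_percent_change(y, des, tr = 4, regressor = rep(1, n)),
               "zero variance")
})

test_that("boxcar GLM recovers a +5% effect under noise", {
  des <- task_design(n_blocks = 3, block_s = 40,
                     rest_choices_s = c(32, 40), tr = 4, seed = 2)
  n <- floor(des$total_duration / 4)
  box <- boxcar_regressor(des, n, 4)
  truth <- 5
  set.seed(11)
  # 100 replicate series at response-amplitude SNR 20
  Y <- matrix(100 + truth * box, n, 100) +
    matrix(rnorm(n * 100, sd = truth / 20), n, 100)
  fit <- glm_percent_change(Y, des, tr = 4)
  expect_lt(max(abs(fit$percent_change - truth)), 0.5)
  expect_lt(abs(mean(fit$percent_change) - truth), 0.15)
})
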