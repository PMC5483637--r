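#' @name preprocess
#' @title Temporal preprocessing of dual-echo time series
#' @description Operators applied to voxel time series before the GLM:
#'   spike attenuation, surround subtraction of the interleaved
#'   label/control perfusion echo, pairwise averaging of the BOLD echo,
#'   spatial Gaussian smoothing and discrete-cosine high-pass filtering.
#'   All temporal operators accept either a numeric vector (one voxel) or a
#'   `time x voxel` matrix.
NULL

as_time_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Running mean over `window` time points excluding the centre point;
# edges use whatever part of the window is available.
running_excentre_mean <- function(X, window) {
  half <- window %/% 2L
  n <- nrow(X)
  S <- matrix(0, n, ncol(X))
  C <- numeric(n)
  for (d in seq(-half, half)) {
    if (d == 0L) next
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    S[ok, ] <- S[ok, ] + X[src[ok], , drop = FALSE]
    C[ok] <- C[ok] + 1
  }
  S / C
}

#' Attenuate anomalous points in voxel time series
#'
#' Spikes are detected against a running local reference (the mean of the
#' surrounding `window` time points, centre excluded): a point is flagged
#' when its residual deviates from the median residual by more than
#' `k` robust standard deviations (1.4826 x median absolute deviation of the
#' residuals). Flagged points are replaced by the mean of the nearest
#' non-flagged temporal neighbours. A zero robust scale indicates a locally
#' constant series (e.g. a noiseless simulation), in which case detection is
#' skipped rather than flagging every task transition.
#'
#' @param x Numeric vector (one voxel time series) or `time x voxel` matrix.
#' @param k Detection threshold in robust standard deviations (default 3).
#' @param window Width of the running window in time points (odd, >= 3).
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' despike(c(100, 100, 500, 100, 100))
despike <- function(x, k = 3, window = 5L) {
  stopifnot(k > 0, window >= 3L, window %% 2L == 1L)
  X <- as_time_matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("time series must have length >= 3")
  ref <- running_excentre_mean(X, window)
  R <- X - ref
  med <- apply(R, 2L, median)
  scl <- 1.4826 * apply(abs(sweep(R, 2L, med)), 2L, median)
  out <- X
  for (j in seq_len(ncol(X))) {
    if (scl[j] <= 0) next
    bad <- which(abs(R[, j] - med[j]) > k * scl[j])
    if (!length(bad)) next
    good <- setdiff(seq_len(n), bad)
    if (!length(good)) next
    for (t in bad) {
      lo <- good[good < t]
      hi <- good[good > t]
      nb <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
      out[t, j] <- mean(X[nb, j])
    }
  }
  if (is.matrix(x)) out else drop(out)
}

# TRUE for the volumes that are label acquisitions.
label_parity <- function(n, label_first) {
  if (label_first) (seq_len(n) %% 2L) == 1L else (seq_len(n) %% 2L) == 0L
}

#' Surround subtraction of an interleaved label/control perfusion echo
#'
#' Reconstructs a perfusion-weighted (control minus label) time series at
#' every time point from an echo in which label and control volumes
#' alternate: each volume is differenced against the mean of its two
#' temporal neighbours (the opposite condition), with the sign chosen per
#' parity so that true perfusion comes out non-negative. Endpoints use the
#' single available neighbour. Linear drifts shared by the two conditions
#' cancel at interior points.
#'
#' @param x Numeric vector, `time x voxel` matrix, or 4D array (x,y,z,t).
#' @param label_first Is the first volume a label acquisition?
#' @return Perfusion-weighted series, same shape and length as the input.
#' @export
surround_subtract <- function(x, label_first = TRUE) {
  if (is.array(x) && length(dim(x)) == 4L) {
    d <- dim(x)
    out <- apply_time_matrix(x, function(X) surround_subtract(X, label_first))
    return(out)
  }
  X <- as_time_matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("surround subtraction needs at least 3 volumes")
  nb <- X
  nb[2:(n - 1), ] <- (X[1:(n - 2), , drop = FALSE] +
                        X[3:n, , drop = FALSE]) / 2
  nb[1, ] <- X[2, ]
  nb[n, ] <- X[n - 1, ]
  s <- ifelse(label_parity(n, label_first), -1, 1)
  out <- s * (X - nb)
  if (is.matrix(x)) out else drop(out)
}

#' Pairwise averaging of temporally adjacent BOLD volumes
#'
#' Removes the label/control ripple from the BOLD echo by replacing each
#' volume with the average of itself and its successor; the final volume is
#' carried unchanged, so the output length equals the input length.
#'
#' @inheritParams surround_subtract
#' @return Averaged series, same shape as the input.
#' @export
bold_pair_average <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) {
    return(apply_time_matrix(x, bold_pair_average))
  }
  X <- as_time_matrix(x)
  n <- nrow(X)
  if (n < 2L) stop("pair averaging needs at least 2 volumes")
  out <- X
  out[1:(n - 1), ] <- (X[1:(n - 1), , drop = FALSE] + X[2:n, , drop = FALSE]) / 2
  if (is.matrix(x)) out else drop(out)
}

# Run a time x voxel matrix operation over a 4D array.
apply_time_matrix <- function(arr, fun) {
  d <- dim(arr)
  X <- t(matrix(arr, prod(d[1:3]), d[4]))  # time x voxel
  Y <- fun(X)
  array(t(Y), dim = d)
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# 1D convolution along the rows of a matrix with edge renormalisation
# (constant inputs stay constant).
convolve_axis <- function(M, kernel) {
  if (length(kernel) == 1L) return(M)
  n <- nrow(M)
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1L & idx <= n
    K[i, idx[ok]] <- kernel[ok] / sum(kernel[ok])
  }
  K %*% M
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing of a 3D volume or of every volume of a 4D
#' series, with `sigma = fwhm / 2.3548` per axis converted to voxel units.
#' Kernels are renormalised at the volume edges so that constant volumes are
#' unchanged; `fwhm_mm = 0` is the identity.
#'
#' @param x 3D array or 4D array (x,y,z,t).
#' @param fwhm_mm Full width at half maximum of the kernel, millimetres.
#' @param voxel_size_mm Voxel edge lengths in mm, length 3.
#' @return Smoothed array, same shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 8, voxel_size_mm = c(3.44, 3.44, 5)) {
  stopifnot(fwhm_mm >= 0, length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  if (length(d) == 4L) {
    out <- x
    for (t in seq_len(d[4])) {
      out[, , , t] <- smooth_gaussian(x[, , , t, drop = TRUE], fwhm_mm,
                                      voxel_size_mm)
    }
    return(out)
  }
  stopifnot(length(d) == 3L)
  sigma <- fwhm_mm / 2.3548 / voxel_size_mm
  v <- x
  # axis 1
  v <- array(convolve_axis(matrix(v, d[1], d[2] * d[3]), gaussian_kernel(sigma[1])), d)
  # axis 2
  v <- aperm(array(convolve_axis(matrix(aperm(v, c(2, 1, 3)), d[2], d[1] * d[3]),
                                 gaussian_kernel(sigma[2])), d[c(2, 1, 3)]),
             c(2, 1, 3))
  # axis 3
  v <- aperm(array(convolve_axis(matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2]),
                                 gaussian_kernel(sigma[3])), d[c(3, 1, 2)]),
             c(2, 3, 1))
  v
}

dct_basis <- function(n, n_comp) {
  t <- seq_len(n) - 0.5
  sapply(seq_len(n_comp), function(k) cos(pi * k * t / n))
}

#' Temporal high-pass filter (discrete-cosine projection)
#'
#' Removes slow drifts by projecting out the discrete-cosine components with
#' frequency below `cutoff_hz` (frequency of component `k` over `n` volumes:
#' `k / (2 n tr)`), then re-adding the series mean so the baseline level is
#' preserved. Any filter meeting the attenuation contract (>= 90% below the
#' cutoff, < 5% at the task frequency) is interchangeable with this one.
#'
#' @param x Numeric vector or `time x voxel` matrix.
#' @param cutoff_hz High-pass cutoff in Hz; must be below Nyquist.
#' @param tr Repetition time in seconds.
#' @return Filtered series, same shape as `x`.
#' @export
highpass <- function(x, cutoff_hz = 0.0039, tr = 4) {
  stopifnot(cutoff_hz > 0, tr > 0)
  if (cutoff_hz >= 1 / (2 * tr)) {
    stop("'cutoff_hz' must be below the Nyquist frequency 1/(2*tr)")
  }
  X <- as_time_matrix(x)
  n <- nrow(X)
  n_comp <- floor(2 * n * tr * cutoff_hz)
  mu <- colMeans(X)
  if (n_comp >= 1L) {
    B <- cbind(1, dct_basis(n, n_comp))
    Q <- qr.Q(qr(B))
    X <- X - Q %*% (t(Q) %*% X)
  } else {
    X <- sweep(X, 2L, mu)
  }
  out <- sweep(X, 2L, mu, `+`)
  if (is.matrix(x)) out else drop(out)
}

#' Boxcar task regressor
#'
#' Samples the block design at volume acquisition times `(t-1) * tr`:
#' 1 inside a stimulation block, 0 at rest.
#'
#' @param design A [task_design()] object.
#' @param n_vol Number of volumes.
#' @param tr Repetition time in seconds.
#' @return Numeric 0/1 vector of length `n_vol`.
#' @export
boxcar_regressor <- function(design, n_vol, tr) {
  times <- (seq_len(n_vol) - 1) * tr
  box <- numeric(n_vol)
  for (i in seq_along(design$block_onsets)) {
    on <- design$block_onsets[i]
    box[times >= on & times < on + design$block_duration] <- 1
  }
  box
}

#' Percent signal change and t-statistic from a boxcar GLM
#'
#' Least-squares fit of `[intercept, regressor]`; the task effect is scaled
#' to the voxel's resting baseline (the intercept) and multiplied by 100 to
#' give percent signal change. The t-statistic of the task coefficient is
#' also returned for ROI ranking. When the residual variance is zero
#' (noiseless simulations) the t-statistic is capped at `1e12` with the sign
#' of the effect; a zero effect with zero variance gives t = 0.
#'
#' @param x Numeric vector or `time x voxel` matrix.
#' @param design A [task_design()] object (ignored when `regressor` given).
#' @param tr Repetition time in seconds.
#' @param regressor Optional explicit task regressor (e.g. the boxcar passed
#'   through the same temporal operators as the data).
#' @return For a vector input, a list with `percent_change` and `t`;
#'   for a matrix, a list of two vectors (one entry per voxel).
#' @export
glm_percent_change <- function(x, design = NULL, tr = 4, regressor = NULL) {
  X <- as_time_matrix(x)
  n <- nrow(X)
  if (is.null(regressor)) {
    if (is.null(design)) stop("either 'design' or 'regressor' is required")
    regressor <- boxcar_regressor(design, n, tr)
  }
  stopifnot(length(regressor) == n)
  if (var(regressor) == 0) stop("task regressor has zero variance")
  D <- cbind(1, regressor)
  XtX <- crossprod(D)
  B <- solve(XtX, crossprod(D, X))          # 2 x V
  res <- X - D %*% B
  df <- n - 2L
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  # numerically-zero effects and residuals (noiseless series) are treated
  # as exact zeros rather than ratios of rounding error
  scale <- colMeans(abs(X)) + .Machine$double.eps
  b1 <- ifelse(abs(B[2, ]) < 1e-9 * scale, 0, B[2, ])
  se <- ifelse(se < 1e-9 * scale, 0, se)
  tstat <- ifelse(se > 0, b1 / se, ifelse(b1 == 0, 0, sign(b1) * 1e12))
  # saturate numerically-perfect fits at one common value so downstream
  # quantile selection treats them as ties rather than ranking float jitter
  tstat[tstat > 1e9] <- 1e12
  tstat[tstat < -1e9] <- -1e12
  baseline <- B[1, ]
  if (any(baseline <= 0)) {
    warning("non-positive baseline estimate in ", sum(baseline <= 0),
            " voxel(s); percent change set to NA there")
  }
  pct <- ifelse(baseline > 0, 100 * b1 / baseline, NA_real_)
  pct <- unname(pct)
  tstat <- unname(tstat)
  if (is.matrix(x)) {
    list(percent_change = pct, t = tstat)
  } else {
    list(percent_change = pct[1L], t = tstat[1L])
  }
}
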