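#' Davis model constants
#'
#' Container for the two dimensionless constants of the Davis biophysical
#' model of the BOLD signal: `alpha`, the exponent of the power-law coupling
#' between cerebral blood flow and cerebral blood volume (Grubb exponent),
#' and `beta`, a field-strength-dependent exponent summarising the
#' susceptibility effect of deoxyhemoglobin. The defaults (`alpha = 0.38`,
#' `beta = 1.3`) are the values conventionally used for 3 T acquisitions.
#'
#' All model functions work with *fractional* changes from baseline
#' (`delta = 0.02` means +2%); the corresponding baseline ratio is
#' `1 + delta`. Percent scaling is applied only at reporting boundaries.
#'
#' @param alpha Flow-volume coupling exponent, > 0.
#' @param beta Deoxyhemoglobin susceptibility exponent, > 0.
#' @return An object of class `davis_params`.
#' @export
#' @examples
#' davis_params()
davis_params <- function(alpha = 0.38, beta = 1.3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0) stop("'alpha' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  structure(list(alpha = alpha, beta = beta), class = "davis_params")
}

#' @export
print.davis_params <- function(x, ...) {
  cat(sprintf("Davis model constants: alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

check_ratio <- function(delta, name) {
  if (any(!is.finite(delta))) {
    stop(sprintf("'%s' contains non-finite values", name))
  }
  if (any(1 + delta <= 0)) {
    stop(sprintf("'%s' implies a non-positive baseline ratio (1 + %s <= 0)",
                 name, name))
  }
  invisible(delta)
}

#' Forward Davis model: predicted BOLD change
#'
#' Predicts the fractional BOLD signal change produced by given fractional
#' changes in CBF and CMRO2 under the Davis model,
#' \deqn{\Delta BOLD/BOLD_0 = M (1 - (1+\delta_{CBF})^{\alpha-\beta}
#'       (1+\delta_{CMRO_2})^{\beta}).}
#' This is the exact algebraic inverse of [compute_delta_cmro2()].
#'
#' @param delta_cbf Fractional CBF change(s) from baseline.
#' @param delta_cmro2 Fractional CMRO2 change(s) from baseline.
#' @param m Calibration constant M as a fraction (>= 0).
#' @param params A [davis_params()] object.
#' @return Fractional BOLD change(s), same length as the inputs.
#' @export
#' @examples
#' forward_bold(1.0, 0, m = 0.05)  # flow doubles, metabolism unchanged
forward_bold <- function(delta_cbf, delta_cmro2, m, params = davis_params()) {
  stopifnot(inherits(params, "davis_params"))
  if (any(m < 0)) stop("'m' must be non-negative")
  check_ratio(delta_cbf, "delta_cbf")
  check_ratio(delta_cmro2, "delta_cmro2")
  m * (1 - (1 + delta_cbf)^(params$alpha - params$beta) *
         (1 + delta_cmro2)^params$beta)
}

#' Estimate the calibration constant M from a hypercapnic challenge
#'
#' Under hypercapnia CBF rises while CMRO2 is assumed unchanged, so the Davis
#' model can be solved for M:
#' \deqn{M = \frac{(BOLD_{hc}-BOLD_0)/BOLD_0}
#'                {1 - (1 + (CBF_{hc}-CBF_0)/CBF_0)^{\alpha-\beta}}.}
#' Only the two ratios enter, so the result is invariant to rescaling the
#' BOLD and CBF signals by positive constants.
#'
#' @param bold_0,bold_hc Mean BOLD signal during normocapnia / hypercapnia.
#' @param cbf_0,cbf_hc Mean perfusion-weighted signal during normocapnia /
#'   hypercapnia (`bold_0 > 0`, `cbf_0 > 0`).
#' @param params A [davis_params()] object.
#' @return M as a fraction (multiply by 100 for percent).
#' @export
#' @examples
#' estimate_m(100, 102, 50, 100)  # +2% BOLD, +100% CBF
estimate_m <- function(bold_0, bold_hc, cbf_0, cbf_hc,
                       params = davis_params()) {
  stopifnot(inherits(params, "davis_params"))
  if (any(bold_0 <= 0)) stop("'bold_0' must be positive")
  if (any(cbf_0 <= 0)) stop("'cbf_0' must be positive")
  delta_bold <- (bold_hc - bold_0) / bold_0
  delta_cbf <- (cbf_hc - cbf_0) / cbf_0
  if (any(delta_cbf == 0)) {
    stop("hypercapnic CBF change is zero: calibration undefined")
  }
  check_ratio(delta_cbf, "delta_cbf")
  delta_bold / (1 - (1 + delta_cbf)^(params$alpha - params$beta))
}

#' Task-evoked fractional CMRO2 change
#'
#' Inverts the Davis model for the fractional CMRO2 change given measured
#' fractional BOLD and CBF changes and the calibration constant M:
#' \deqn{\Delta CMRO_2/CMRO_2|_0 = (1 - \delta_{BOLD}/M)^{1/\beta}
#'       (1+\delta_{CBF})^{1-\alpha/\beta} - 1.}
#'
#' @param delta_bold Fractional BOLD change(s); must satisfy
#'   `delta_bold < m` (the BOLD ceiling).
#' @param delta_cbf Fractional CBF change(s).
#' @param m Calibration constant M as a fraction, > 0.
#' @param params A [davis_params()] object.
#' @return Fractional CMRO2 change(s).
#' @export
#' @examples
#' compute_delta_cmro2(0.0118, 0.9268, m = 0.0511)
compute_delta_cmro2 <- function(delta_bold, delta_cbf, m,
                                params = davis_params()) {
  stopifnot(inherits(params, "davis_params"))
  if (any(m <= 0)) stop("'m' must be positive: calibration missing or invalid")
  if (any(delta_bold / m >= 1)) {
    stop("'delta_bold' reaches or exceeds the BOLD ceiling M; ",
         "CMRO2 change undefined")
  }
  check_ratio(delta_cbf, "delta_cbf")
  (1 - delta_bold / m)^(1 / params$beta) *
    (1 + delta_cbf)^(1 - params$alpha / params$beta) - 1
}

#' Flow-metabolism coupling ratio n
#'
#' The neural-vascular coupling ratio, the fractional CBF change per unit
#' fractional CMRO2 change: `n = delta_cbf / delta_cmro2`.
#'
#' @param delta_cbf Fractional CBF change(s).
#' @param delta_cmro2 Fractional CMRO2 change(s); must be non-zero.
#' @return Coupling ratio(s).
#' @export
compute_n <- function(delta_cbf, delta_cmro2) {
  if (any(delta_cmro2 == 0)) {
    stop("'delta_cmro2' is zero: coupling ratio undefined")
  }
  delta_cbf / delta_cmro2
}
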