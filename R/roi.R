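#' Grey-matter mask from a partial-volume map
#'
#' Retains voxels whose grey-matter partial volume estimate is at or above
#' the threshold (inclusive inequality).
#'
#' @param pve_gm 3D array of grey-matter partial volume estimates in `[0, 1]`.
#' @param threshold Retention threshold (default 0.80).
#' @return Logical array of the same shape.
#' @export
grey_matter_mask <- function(pve_gm, threshold = 0.80) {
  if (any(pve_gm < 0 | pve_gm > 1, na.rm = TRUE)) {
    stop("partial volume estimates must lie in [0, 1]")
  }
  pve_gm >= threshold
}

# Inclusive top-fraction threshold within a set of values.
top_fraction_select <- function(values, top_fraction) {
  thr <- quantile(values, probs = 1 - top_fraction, names = FALSE, type = 7)
  values >= thr
}

#' Task functional ROI: overlap of top BOLD and CBF t-values
#'
#' Within the structural mask, thresholds each t-map at its
#' `1 - top_fraction` quantile (ties at the threshold are included) and
#' returns the intersection of the two suprathreshold sets. The resulting
#' task-responsive ROI is where the evoked measures are averaged.
#'
#' @param t_bold,t_cbf 3D t-statistic maps on the same grid.
#' @param structural_mask Logical 3D array (e.g. occipital grey matter).
#' @param top_fraction Fraction of the mask retained per map (default 0.05).
#' @return Logical ROI array with attribute `n_voxels`.
#' @export
functional_roi <- function(t_bold, t_cbf, structural_mask,
                           top_fraction = 0.05) {
  stopifnot(all(dim(t_bold) == dim(structural_mask)),
            all(dim(t_cbf) == dim(structural_mask)),
            top_fraction > 0, top_fraction <= 1)
  inside <- which(structural_mask)
  if (!length(inside)) stop("structural mask is empty")
  sel <- top_fraction_select(t_bold[inside], top_fraction) &
    top_fraction_select(t_cbf[inside], top_fraction)
  if (!any(sel)) {
    stop("functional ROI is empty: top-", top_fraction * 100,
         "% BOLD and CBF sets do not overlap; consider a larger fraction")
  }
  roi <- array(FALSE, dim(structural_mask))
  roi[inside[sel]] <- TRUE
  attr(roi, "n_voxels") <- sum(sel)
  roi
}

# Volume indices fully inside [from_s, to_s) with both temporal neighbours
# also inside: a one-volume guard so 3-point temporal operators (surround
# subtraction, pair averaging) never mix data across window boundaries.
window_volumes <- function(n_vol, tr, from_s, to_s) {
  times <- (seq_len(n_vol) - 1) * tr
  inside <- times >= from_s & times < to_s
  core <- inside &
    c(FALSE, inside[-n_vol]) &
    c(inside[-1], FALSE)
  which(core)
}

#' Hypercapnic gas-challenge ROI and calibration summary
#'
#' Processes a task-free normocapnia-to-hypercapnia dual-echo run into
#' per-voxel fractional change maps, selects a calibration ROI, and
#' estimates M. Steps: despike, surround-subtract the perfusion echo,
#' pair-average the BOLD echo, smooth; average each voxel over the room-air
#' window (baseline) and over the final `hc_avg_s` seconds of hypercapnia
#' (the first `hc_discard_s` seconds after gas onset are discarded while
#' blood flow stabilises); form `delta = (hc - baseline)/baseline` maps; the
#' ROI is the overlap of the top `top_fraction` of the two delta maps within
#' the structural mask, escalated to `fallback_fraction` when the overlap
#' has fewer than `min_voxels` voxels. ROI-mean signals give M via
#' [estimate_m()]. The high-pass filter is deliberately not applied here:
#' the quantity of interest is the sustained step between the two windows,
#' which a 0.0039 Hz filter would attenuate.
#'
#' @param series A `dual_echo_series` (see [make_gas_run()]).
#' @param structural_mask Logical 3D array.
#' @param baseline_s Duration of room-air breathing at the start, seconds.
#' @param hc_discard_s Seconds of hypercapnia discarded after gas onset.
#' @param hc_avg_s Seconds averaged at the end of the run.
#' @param top_fraction,fallback_fraction ROI retention fractions.
#' @param min_voxels Minimum acceptable overlap before escalating.
#' @param params A [davis_params()] object.
#' @param fwhm_mm,despike_k Preprocessing parameters.
#' @return A list of class `gas_summary`: ROI-mean `bold_0`, `bold_hc`,
#'   `cbf_0`, `cbf_hc`, fractional `delta_bold_hc`, `delta_cbf_hc`, `m`,
#'   `m_percent`, `roi_voxels`, `top_fraction_used` and the ROI mask.
#' @export
gas_roi_and_summary <- function(series, structural_mask,
                                baseline_s = 240, hc_discard_s = 120,
                                hc_avg_s = 240,
                                top_fraction = 0.15,
                                fallback_fraction = 0.20,
                                min_voxels = 10L,
                                params = davis_params(),
                                fwhm_mm = 8, despike_k = 3) {
  stopifnot(inherits(series, "dual_echo_series"))
  d <- dim(series$bold_echo)
  tr <- series$tr
  n_vol <- d[4]
  total_s <- n_vol * tr
  if (baseline_s < 240 - 1e-9) {
    stop("gas run must contain at least 4 min of room-air baseline")
  }
  if (total_s - baseline_s < 360 - 1e-9) {
    stop("gas run must contain at least 6 min of hypercapnia")
  }

  vox <- series$voxel_size_mm
  times <- (seq_len(n_vol) - 1) * tr
  step <- as.numeric(times >= baseline_s)
  lab <- as.numeric(label_parity(n_vol, series$label_first))
  bold <- apply_time_matrix(series$bold_echo, function(X)
    bold_pair_average(despike_model(X, step, k = despike_k)))
  cbf <- apply_time_matrix(series$perfusion_echo, function(X)
    surround_subtract(despike_model(X, cbind(step, lab, lab * step),
                                    k = despike_k),
                      series$label_first))
  bold <- smooth_gaussian(bold, fwhm_mm, vox)
  cbf <- smooth_gaussian(cbf, fwhm_mm, vox)

  idx0 <- window_volumes(n_vol, tr, 0, baseline_s)
  idx1 <- window_volumes(n_vol, tr, total_s - hc_avg_s, total_s)
  if ((min(idx1) - 1) * tr <= baseline_s + hc_discard_s) {
    stop("hypercapnia averaging window overlaps the discarded stabilisation period")
  }

  mean_over <- function(arr, idx) {
    apply(arr[, , , idx, drop = FALSE], c(1, 2, 3), mean)
  }
  bold_0_map <- mean_over(bold, idx0)
  bold_hc_map <- mean_over(bold, idx1)
  cbf_0_map <- mean_over(cbf, idx0)
  cbf_hc_map <- mean_over(cbf, idx1)

  inside <- which(structural_mask)
  if (!length(inside)) stop("structural mask is empty")
  db <- (bold_hc_map[inside] - bold_0_map[inside]) / bold_0_map[inside]
  dc <- (cbf_hc_map[inside] - cbf_0_map[inside]) / cbf_0_map[inside]

  pick <- function(fr) top_fraction_select(db, fr) & top_fraction_select(dc, fr)
  used <- top_fraction
  sel <- pick(used)
  if (sum(sel) < min_voxels) {
    used <- fallback_fraction
    sel <- pick(used)
  }
  if (!any(sel)) {
    stop("gas calibration failed: no overlap of top delta-BOLD and ",
         "delta-CBF voxels even at the fallback fraction")
  }
  roi <- array(FALSE, d[1:3])
  roi[inside[sel]] <- TRUE

  vals <- list(bold_0 = mean(bold_0_map[roi]),
               bold_hc = mean(bold_hc_map[roi]),
               cbf_0 = mean(cbf_0_map[roi]),
               cbf_hc = mean(cbf_hc_map[roi]))
  m <- estimate_m(vals$bold_0, vals$bold_hc, vals$cbf_0, vals$cbf_hc, params)
  structure(c(vals, list(
    delta_bold_hc = (vals$bold_hc - vals$bold_0) / vals$bold_0,
    delta_cbf_hc = (vals$cbf_hc - vals$cbf_0) / vals$cbf_0,
    m = m,
    m_percent = 100 * m,
    roi_voxels = sum(sel),
    top_fraction_used = used,
    roi = roi
  )), class = "gas_summary")
}

#' @export
print.gas_summary <- function(x, ...) {
  cat(sprintf(
    "Gas-challenge calibration: M = %.3f%% (dBOLD = %.3f%%, dCBF = %.1f%%), %d ROI voxels (top %.0f%%)\n",
    x$m_percent, 100 * x$delta_bold_hc, 100 * x$delta_cbf_hc,
    x$roi_voxels, 100 * x$top_fraction_used))
  invisible(x)
}

#' Visual-evoked measures within a functional ROI
#'
#' Combines fractional change maps with the calibration constant M into the
#' four evoked measures. In `"voxelwise"` mode (the default) CMRO2 change
#' and the coupling ratio n are computed per ROI voxel and then averaged,
#' skipping (with a count) voxels whose BOLD change reaches the ceiling M;
#' in `"roi_mean"` mode the delta maps are averaged first and the model is
#' applied once. veBOLD and veCBF are ROI means scaled to percent. The two
#' modes agree exactly on spatially uniform maps and differ on heterogeneous
#' ones because the model is non-linear.
#'
#' @param delta_bold,delta_cbf 3D fractional change maps.
#' @param roi Logical ROI array.
#' @param m Calibration constant (fraction, > 0).
#' @param params A [davis_params()] object.
#' @param mode `"voxelwise"` or `"roi_mean"`.
#' @return A list of class `evoked_measures`: `ve_bold`, `ve_cbf`,
#'   `ve_cmro2` (percent), `ve_n` (ratio), `roi_voxels`, `n_skipped`.
#' @export
evoked_measures <- function(delta_bold, delta_cbf, roi, m,
                            params = davis_params(),
                            mode = c("voxelwise", "roi_mean")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(delta_bold) == dim(roi)), all(dim(delta_cbf) == dim(roi)))
  if (m <= 0) stop("'m' must be positive")
  db <- delta_bold[roi]
  dc <- delta_cbf[roi]
  if (!length(db)) stop("ROI is empty")

  if (mode == "voxelwise") {
    ok <- db / m < 1 & (1 + dc) > 0 & is.finite(db) & is.finite(dc)
    n_skipped <- sum(!ok)
    if (!any(ok)) stop("all ROI voxels violate the model preconditions")
    dm <- compute_delta_cmro2(db[ok], dc[ok], m, params)
    nz <- dm != 0
    ve_cmro2 <- mean(dm)
    ve_n <- if (any(nz)) mean(compute_n(dc[ok][nz], dm[nz])) else NA_real_
  } else {
    n_skipped <- 0L
    dm <- compute_delta_cmro2(mean(db), mean(dc), m, params)
    ve_cmro2 <- dm
    ve_n <- compute_n(mean(dc), dm)
  }
  structure(list(
    ve_bold = 100 * mean(db),
    ve_cbf = 100 * mean(dc),
    ve_cmro2 = 100 * ve_cmro2,
    ve_n = ve_n,
    roi_voxels = length(db),
    n_skipped = as.integer(n_skipped),
    mode = mode
  ), class = "evoked_measures")
}

#' @export
print.evoked_measures <- function(x, ...) {
  cat(sprintf(
    "Evoked measures (%s, %d voxels%s): veBOLD %.3f%%, veCBF %.2f%%, veCMRO2 %.2f%%, ven %.3f\n",
    x$mode, x$roi_voxels,
    if (x$n_skipped > 0) sprintf(", %d skipped", x$n_skipped) else "",
    x$ve_bold, x$ve_cbf, x$ve_cmro2, x$ve_n))
  invisible(x)
}

# Despike against the expected signal: remove the known experimental
# structure (task boxcar / hypercapnic step, and the label/control
# alternation of the perfusion echo), despike the residuals, add the fit
# back. Detecting on raw series would flag genuine signal transitions as
# spikes whenever the per-volume noise is small relative to the response.
# The reference per design cell is the cell median, so gross corruption of
# a minority of volumes cannot drag the reference of the clean ones.
despike_model <- function(X, regressors, k) {
  cells <- interaction(as.data.frame(cbind(regressors)), drop = TRUE)
  fit <- X
  for (lv in levels(cells)) {
    rows <- which(cells == lv)
    med <- apply(X[rows, , drop = FALSE], 2L, median)
    fit[rows, ] <- rep(med, each = length(rows))
  }
  fit + despike(X - fit, k = k)
}

# The boxcar as it appears in the surround-subtracted perfusion series:
# sampled at label volumes, interpolated from the neighbouring labels at
# control volumes (endpoints use the single neighbour).
surround_design <- function(box, label_first) {
  n <- length(box)
  lab <- label_parity(n, label_first)
  nb <- box
  idx <- 2:(n - 1)
  nb[idx] <- (box[idx - 1] + box[idx + 1]) / 2
  nb[1] <- box[2]
  nb[n] <- box[n - 1]
  ifelse(lab, box, nb)
}

#' Task-run fractional change and t-statistic maps
#'
#' Full single-run preprocessing chain: despike both echoes,
#' surround-subtract the perfusion echo / pair-average the BOLD echo,
#' smooth spatially, high-pass filter, then fit the boxcar GLM per voxel.
#' The task regressor is passed through the same temporal operators as the
#' data it models (label/control sampling for the perfusion echo, pair
#' averaging for the BOLD echo, then the high-pass filter), so the fit is
#' unbiased at task-block transitions.
#'
#' @param series A `dual_echo_series` with an attached task design.
#' @param fwhm_mm,highpass_hz,despike_k Preprocessing parameters.
#' @return A list with 3D maps `delta_bold`, `delta_cbf` (fractions) and
#'   `t_bold`, `t_cbf`.
#' @export
task_maps <- function(series, fwhm_mm = 8, highpass_hz = 0.0039,
                      despike_k = 3) {
  stopifnot(inherits(series, "dual_echo_series"))
  d <- dim(series$bold_echo)
  tr <- series$tr
  n_vol <- d[4]
  box <- boxcar_regressor(series$design, n_vol, tr)
  vox <- series$voxel_size_mm

  lab <- as.numeric(label_parity(n_vol, series$label_first))
  bold <- apply_time_matrix(series$bold_echo, function(X)
    bold_pair_average(despike_model(X, box, k = despike_k)))
  cbf <- apply_time_matrix(series$perfusion_echo, function(X)
    surround_subtract(despike_model(X, cbind(box, lab, lab * box),
                                    k = despike_k),
                      series$label_first))
  bold <- smooth_gaussian(bold, fwhm_mm, vox)
  cbf <- smooth_gaussian(cbf, fwhm_mm, vox)

  reg_bold <- highpass(bold_pair_average(box), highpass_hz, tr)
  reg_cbf <- highpass(surround_design(box, series$label_first), highpass_hz, tr)

  to_mat <- function(arr) t(matrix(arr, prod(d[1:3]), d[4]))
  fit_maps <- function(arr, reg) {
    Y <- highpass(to_mat(arr), highpass_hz, tr)
    fit <- glm_percent_change(Y, tr = tr, regressor = reg)
    list(delta = array(fit$percent_change / 100, d[1:3]),
         t = array(fit$t, d[1:3]))
  }
  fb <- fit_maps(bold, reg_bold)
  fc <- fit_maps(cbf, reg_cbf)
  list(delta_bold = fb$delta, t_bold = fb$t,
       delta_cbf = fc$delta, t_cbf = fc$t)
}

#' Per-participant evoked measures from task + gas runs
#'
#' Ties the pipeline together for one participant: builds the structural
#' mask (occipital ROI intersected with grey matter at >= 80% partial
#' volume), extracts task delta/t maps, forms the functional ROI from the
#' overlapping top t-values, calibrates M from the gas run, and returns the
#' evoked measures.
#'
#' @param task_series,gas_series `dual_echo_series` objects on one grid.
#' @param gm_pve 3D grey-matter partial volume map.
#' @param occipital_mask Logical 3D occipital ROI.
#' @param config A [run_config()] object.
#' @return A list with elements `evoked` ([evoked_measures()]), `gas`
#'   ([gas_roi_and_summary()]), `roi` and `structural_mask`.
#' @export
evoked_participant <- function(task_series, gas_series, gm_pve,
                               occipital_mask, config = run_config()) {
  same_grid <- function(a, b) length(a) == length(b) && all(a == b)
  grid <- dim(task_series$bold_echo)[1:3]
  if (!same_grid(dim(gas_series$bold_echo)[1:3], grid) ||
      !same_grid(dim(gm_pve), grid) || !same_grid(dim(occipital_mask), grid)) {
    stop("all inputs must share one voxel grid (registration is assumed done)")
  }
  structural <- occipital_mask & grey_matter_mask(gm_pve, config$gm_pve_threshold)
  if (!any(structural)) stop("structural mask (occipital grey matter) is empty")

  maps <- task_maps(task_series, fwhm_mm = config$fwhm_mm,
                    highpass_hz = config$highpass_hz,
                    despike_k = config$despike_k)
  roi <- functional_roi(maps$t_bold, maps$t_cbf, structural,
                        top_fraction = config$roi_top_fraction)
  gas <- gas_roi_and_summary(gas_series, structural,
                             top_fraction = config$gas_top_fraction,
                             fallback_fraction = config$gas_fallback_fraction,
                             min_voxels = config$gas_min_voxels,
                             params = config$davis,
                             fwhm_mm = config$fwhm_mm,
                             despike_k = config$despike_k)
  ev <- evoked_measures(maps$delta_bold, maps$delta_cbf, roi, gas$m,
                        params = config$davis,
                        mode = config$averaging_mode)
  list(evoked = ev, gas = gas, roi = roi, structural_mask = structural)
}
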