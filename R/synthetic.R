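#' Block task design
#'
#' Timing of the visual stimulation task: `n_blocks` stimulation blocks of
#' `block_s` seconds separated (and preceded) by rest periods jittered over
#' `rest_choices_s`. The jitter sequence is drawn once under the seed, so a
#' design is fully determined by `(n_blocks, block_s, rest_choices_s,
#' seed)`; the total run length follows from the drawn sequence rather than
#' being forced to a fixed scan time.
#'
#' @param n_blocks Number of stimulation blocks (default 6).
#' @param block_s Block duration in seconds (default 60).
#' @param rest_choices_s Candidate rest durations in seconds.
#' @param tr Repetition time in seconds (default 4).
#' @param seed Integer seed for the jitter sequence.
#' @return A list of class `task_design`: `block_onsets`,
#'   `block_duration`, `total_duration`, `tr`.
#' @export
task_design <- function(n_blocks = 6L, block_s = 60,
                        rest_choices_s = c(32, 34, 36, 38, 40),
                        tr = 4, seed = 1L) {
  stopifnot(n_blocks >= 1L, block_s > 0, all(rest_choices_s > 0), tr > 0)
  set.seed(seed)
  rests <- sample(rest_choices_s, n_blocks + 1L, replace = TRUE)
  onsets <- cumsum(rests + c(0, rep(block_s, n_blocks)))[seq_len(n_blocks)]
  total <- sum(rests) + n_blocks * block_s
  structure(list(block_onsets = onsets, block_duration = block_s,
                 total_duration = total, tr = tr),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Task design: %d x %gs blocks, onsets %s s, %gs total (TR %gs)\n",
              length(x$block_onsets), x$block_duration,
              paste(x$block_onsets, collapse = ", "),
              x$total_duration, x$tr))
  invisible(x)
}

new_dual_echo <- function(perf, bold, tr, label_first, design, voxel_size,
                          ground_truth) {
  structure(list(perfusion_echo = perf, bold_echo = bold, tr = tr,
                 label_first = label_first, design = design,
                 voxel_size_mm = voxel_size, ground_truth = ground_truth),
            class = "dual_echo_series")
}

#' @export
print.dual_echo_series <- function(x, ...) {
  d <- dim(x$bold_echo)
  cat(sprintf("Dual-echo series: %dx%dx%d grid, %d volumes, TR %gs (%s first)\n",
              d[1], d[2], d[3], d[4], x$tr,
              if (x$label_first) "label" else "control"))
  invisible(x)
}

as_field <- function(value, dims, name) {
  if (length(value) == 1L) return(array(value, dims))
  if (!is.array(value) || !all(dim(value) == dims)) {
    stop(sprintf("'%s' must be a scalar or an array matching the grid", name))
  }
  value
}

#' Smooth spatial field with given mean and spread
#'
#' Spatially smoothed Gaussian noise rescaled to a target mean and standard
#' deviation, clipped to `range`. Used to give synthetic truth maps the
#' smooth spatial heterogeneity of real vascular responses.
#'
#' @param dims Grid dimensions, length 3.
#' @param mean,sd Target field mean and SD.
#' @param range Clipping range (after rescaling).
#' @param smooth_vox Smoothing sigma in voxels.
#' @param seed Integer seed.
#' @return 3D array.
#' @export
structured_field <- function(dims, mean = 1.5, sd = 0.4,
                             range = c(0.2, 3), smooth_vox = 2, seed = 1L) {
  set.seed(seed)
  f <- array(rnorm(prod(dims)), dims)
  f <- smooth_gaussian(f, fwhm_mm = 2.3548 * smooth_vox, voxel_size_mm = c(1, 1, 1))
  f <- (f - mean(f)) / sd(f) * sd + mean
  pmin(pmax(f, range[1]), range[2])
}

# Shared noise model for the two echoes. `snr` is the contrast-to-noise
# ratio of the evoked (or hypercapnic) response: white noise is scaled so
# that the response amplitude of each contrast -- `mean(|delta_bold|) *
# base_bold` in the BOLD echo, `mean(|delta_cbf|) * base_perfusion` in the
# surround-subtracted perfusion difference signal -- is `snr` times the
# noise SD of that contrast's series. A zero-response contrast is
# generated noiseless.
echo_noise_sd <- function(db, dc, base_bold, base_perfusion, snr) {
  if (!is.finite(snr)) return(c(bold = 0, perf = 0))
  c(bold = mean(abs(db)) * base_bold / snr,
    perf = mean(abs(dc)) * base_perfusion / (snr * sqrt(1.5)))
}

build_dual_echo <- function(modulation, delta_bold, delta_cbf, dims,
                            voxel_size, tr, base_bold, base_perfusion,
                            snr, label_first, design, seed, truth_extra) {
  n_vol <- length(modulation)
  db <- as_field(delta_bold, dims, "delta_bold")
  dc <- as_field(delta_cbf, dims, "delta_cbf")
  nv <- prod(dims)
  sds <- echo_noise_sd(db, dc, base_bold, base_perfusion, snr)
  set.seed(seed)

  lab <- label_parity(n_vol, label_first)
  bold <- array(0, c(dims, n_vol))
  perf <- array(0, c(dims, n_vol))
  for (t in seq_len(n_vol)) {
    bold[, , , t] <- base_bold * (1 + db * modulation[t])
    p_t <- base_perfusion * (1 + dc * modulation[t])
    perf[, , , t] <- if (lab[t]) base_bold - p_t else base_bold
  }
  if (sds["bold"] > 0) {
    bold <- bold + array(rnorm(nv * n_vol, sd = sds["bold"]), c(dims, n_vol))
  }
  if (sds["perf"] > 0) {
    perf <- perf + array(rnorm(nv * n_vol, sd = sds["perf"]), c(dims, n_vol))
  }
  truth <- c(list(delta_bold = db, delta_cbf = dc,
                  base_bold = base_bold, base_perfusion = base_perfusion,
                  snr = snr, seed = seed), truth_extra)
  new_dual_echo(perf, bold, tr, label_first, design, voxel_size, truth)
}

#' Synthetic dual-echo task run
#'
#' Generates an interleaved label/control perfusion echo and a BOLD echo
#' with known ground truth. The BOLD echo is the baseline signal modulated
#' by `delta_bold` during stimulation blocks; label volumes carry a
#' perfusion deficit of `base_perfusion * (1 + delta_cbf * boxcar)` so the
#' surround-subtracted series recovers the perfusion-weighted signal. The
#' ASL signal model is a simple additive control-label difference (no
#' kinetic model): the pipeline only consumes relative change, for which
#' this is sufficient. `snr` is the contrast-to-noise ratio of the evoked
#' response: the task-induced modulation amplitude of each contrast
#' (BOLD modulation in the BOLD echo; perfusion modulation in the
#' surround-subtracted difference signal) divided by the white-noise SD of
#' that contrast's time series. `snr = Inf` is noiseless.
#'
#' @param delta_bold,delta_cbf Fractional task responses: scalars or 3D
#'   truth maps on the grid.
#' @param design A [task_design()] object.
#' @param dims Grid dimensions (default `c(12, 12, 6)`).
#' @param voxel_size_mm Voxel size (default `c(3.44, 3.44, 5)`).
#' @param base_bold,base_perfusion Baseline signal levels.
#' @param snr Contrast signal-to-noise ratio; `Inf` for noiseless.
#' @param label_first Parity of the first perfusion volume.
#' @param seed Integer seed.
#' @return A `dual_echo_series` carrying its `ground_truth`.
#' @export
make_task_run <- function(delta_bold = 0.012, delta_cbf = 0.7,
                          design = task_design(), dims = c(12, 12, 6),
                          voxel_size_mm = c(3.44, 3.44, 5),
                          base_bold = 1000, base_perfusion = 15,
                          snr = Inf, label_first = TRUE, seed = 1L) {
  n_vol <- floor(design$total_duration / design$tr)
  if (max(design$block_onsets) + design$block_duration >
      n_vol * design$tr + 1e-9) {
    stop("task design exceeds the run length")
  }
  box <- boxcar_regressor(design, n_vol, design$tr)
  build_dual_echo(box, delta_bold, delta_cbf, dims, voxel_size_mm,
                  design$tr, base_bold, base_perfusion, snr, label_first,
                  design, seed, list(kind = "task"))
}

#' Synthetic dual-echo gas-challenge run
#'
#' Normocapnia-to-hypercapnia run with known calibration constant `m`: the
#' hypercapnic CBF rise is `delta_cbf_hc` (scalar or map; default around
#' +150%, in the range reported for occipital grey matter) and the
#' hypercapnic BOLD change follows from the forward Davis model with
#' unchanged CMRO2, so that a correct pipeline recovers `m` exactly on
#' noiseless input. Timing: `baseline_s` of room air followed by
#' hypercapnia to the end of the run.
#'
#' @param m True calibration constant (fraction).
#' @param delta_cbf_hc Hypercapnic fractional CBF change: scalar or 3D map.
#' @param baseline_s Room-air duration in seconds (default 240).
#' @param hc_s Hypercapnia duration in seconds (default 360).
#' @param params A [davis_params()] object.
#' @inheritParams make_task_run
#' @return A `dual_echo_series` carrying its `ground_truth` (including the
#'   implied `delta_bold_hc` map).
#' @export
make_gas_run <- function(m = 0.05, delta_cbf_hc = 1.5,
                         baseline_s = 240, hc_s = 360,
                         params = davis_params(),
                         dims = c(12, 12, 6),
                         voxel_size_mm = c(3.44, 3.44, 5),
                         base_bold = 1000, base_perfusion = 15,
                         snr = Inf, label_first = TRUE, seed = 1L,
                         tr = 4) {
  stopifnot(m >= 0, baseline_s > 0, hc_s > 0)
  dc <- as_field(delta_cbf_hc, dims, "delta_cbf_hc")
  db <- forward_bold(dc, 0, m, params)
  n_vol <- floor((baseline_s + hc_s) / tr)
  times <- (seq_len(n_vol) - 1) * tr
  h <- as.numeric(times >= baseline_s)
  build_dual_echo(h, db, dc, dims, voxel_size_mm, tr, base_bold,
                  base_perfusion, snr, label_first, design = NULL,
                  seed = seed,
                  truth_extra = list(kind = "gas", m = m,
                                     baseline_s = baseline_s, hc_s = hc_s))
}

compact_blob <- function(center, n_voxels, dims) {
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  ord <- order(d2, co[, 1], co[, 2], co[, 3])
  co[ord[seq_len(n_voxels)], , drop = FALSE]
}

#' Synthetic FLAIR lesion phantom
#'
#' Builds a FLAIR volume with a slice-varying baseline intensity, an
#' ellipsoidal brain mask, and hyperintense lesion blobs of exactly known
#' voxel counts planted at given centres. Each lesion is the set of
#' `voxels` grid points nearest its centre (deterministic tie-break), at
#' intensity `baseline + contrast`. With `noise_sd = 0` (the default) the
#' slice-relative threshold rule recovers every planted lesion exactly and
#' flags nothing else; with Gaussian background noise the relative
#' threshold necessarily flags the top tail of the background as well -
#' the false positives that are pruned manually in practice - so noisy
#' phantoms test detection (all planted lesions found), not exactness.
#'
#' @param lesion_spec List of lesions, each `list(center = c(x, y, z),
#'   voxels = k)`; lesions must be disjoint and inside the brain mask.
#' @param dims Grid dimensions (default `c(32, 32, 8)`).
#' @param voxel_size_mm Voxel size (default 1 mm isotropic).
#' @param baseline Mean in-brain intensity per slice (recycled).
#' @param contrast Lesion intensity above the slice baseline.
#' @param noise_sd Gaussian background noise SD (default 0).
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @return A list: `flair`, `brain_mask`, `lesion_mask` (truth),
#'   `voxel_volume_mm3`, `lesion_spec`.
#' @export
make_flair_phantom <- function(lesion_spec = list(),
                               dims = c(32, 32, 8),
                               voxel_size_mm = c(1, 1, 1),
                               baseline = 100, contrast = 60,
                               noise_sd = 0, seed = 1L) {
  voxvol <- prod(voxel_size_mm)
  base_z <- rep_len(baseline, dims[3])
  flair <- array(0, dims)
  for (s in seq_len(dims[3])) flair[, , s] <- base_z[s]

  # ellipsoidal brain
  cx <- (dims + 1) / 2
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  r <- ((co[, 1] - cx[1]) / (0.45 * dims[1]))^2 +
    ((co[, 2] - cx[2]) / (0.45 * dims[2]))^2 +
    ((co[, 3] - cx[3]) / (0.55 * dims[3]))^2
  brain <- array(r <= 1, dims)

  lesions <- array(FALSE, dims)
  for (spec in lesion_spec) {
    stopifnot(length(spec$center) == 3L, spec$voxels >= 1L)
    vox <- compact_blob(spec$center, spec$voxels, dims)
    lin <- vox[, 1] + dims[1] * (vox[, 2] - 1L) + dims[1] * dims[2] * (vox[, 3] - 1L)
    if (any(lesions[lin])) stop("lesion specification overlaps an earlier lesion")
    if (any(!brain[lin])) stop("lesion extends outside the brain mask")
    lesions[lin] <- TRUE
  }
  flair[lesions] <- flair[lesions] + contrast
  if (noise_sd > 0) {
    set.seed(seed)
    flair <- flair + array(rnorm(prod(dims), sd = noise_sd), dims)
  }
  list(flair = flair, brain_mask = brain, lesion_mask = lesions,
       voxel_volume_mm3 = voxvol, lesion_spec = lesion_spec)
}

#' Canonical predictor names
#'
#' The 43 predictor variables of the classification screen: imaging
#' measures (volumetrics, diffusion skeleton averages, lesion burden, the
#' four evoked cfMRI measures), neuropsychological tests, and self-report
#' symptom scales.
#'
#' @return Character vector of length 43.
#' @export
predictor_names <- function() {
  c("normalized_grey_matter_volume", "normalized_white_matter_volume",
    "normalized_whole_brain_volume",
    "skeleton_ad", "skeleton_fa", "skeleton_md", "skeleton_rd",
    "lesion_absolute_volume", "lesion_relative_volume",
    "lesion_distinct_count",
    "ve_bold", "ve_cbf", "ve_cmro2", "ve_n",
    "recall_10_36_delayed", "recall_10_36_immediate",
    "walk_25_foot", "peg_9hole_dominant", "peg_9hole_nondominant",
    "box_completion", "cowat", "number_comparison",
    "pasat_2s", "pasat_3s",
    "srt_delayed", "srt_long_term_storage",
    "symbol_digit_modalities", "trails_a", "trails_b", "trails_b_minus_a",
    "digit_span_backward", "digit_span_forward", "digit_span_total",
    "digit_symbol_coding",
    "mfis_total",
    "sf36_bodily_pain", "sf36_emotion", "sf36_general_health",
    "sf36_mental_health", "sf36_physical_functioning",
    "sf36_role_physical", "sf36_social_functioning", "sf36_vitality")
}

#' Default per-predictor generating distributions
#'
#' Group means and SDs used by [make_participant_table()]. The four evoked
#' cfMRI measures and the gas-challenge quantities use the published group
#' means with SDs back-converted from standard errors (`SD = SEM *
#' sqrt(n)`, n = 10 MS / 13 HC); all remaining predictors default to null
#' standard-normal columns (equal group distributions), which is what the
#' permutation-calibration tests need.
#'
#' @param n_ms,n_hc Group sizes used for the SEM-to-SD conversion.
#' @return Data frame with columns `name`, `mean_ms`, `sd_ms`, `mean_hc`,
#'   `sd_hc`, `null`.
#' @export
default_predictor_spec <- function(n_ms = 10L, n_hc = 13L) {
  sem <- function(se, n) se * sqrt(n)
  informative <- data.frame(
    name = c("ve_bold", "ve_n", "ve_cbf", "ve_cmro2"),
    mean_ms = c(1.12, 4.08, 48.06, 9.59),
    sd_ms = sem(c(0.77, 0.35, 12.58, 0.90), n_ms),
    mean_hc = c(1.18, 4.23, 92.68, 17.85),
    sd_hc = sem(c(0.66, 0.23, 17.29, 1.97), n_hc),
    stringsAsFactors = FALSE
  )
  rest <- setdiff(predictor_names(), informative$name)
  nulls <- data.frame(name = rest, mean_ms = 0, sd_ms = 1,
                      mean_hc = 0, sd_hc = 1, stringsAsFactors = FALSE)
  spec <- rbind(informative, nulls)
  spec$null <- spec$mean_ms == spec$mean_hc & spec$sd_ms == spec$sd_hc
  spec
}

#' Synthetic two-group participant table
#'
#' Draws a participant-by-predictor table with known group-generating
#' distributions: per-group normal draws (or scaled-and-shifted Student t
#' with `df` degrees of freedom when `family = "t"`, to exercise the robust
#' outlier filter).
#'
#' @param n_ms,n_hc Group sizes (default 10 and 13).
#' @param predictor_spec As returned by [default_predictor_spec()]; any
#'   subset of rows is allowed.
#' @param family `"normal"` or `"t"` (heavy-tailed).
#' @param df Degrees of freedom for `family = "t"` (default 3).
#' @param seed Integer seed.
#' @return Data frame with `participant_id`, `group` (factor MS/HC) and one
#'   numeric column per predictor; the generating spec is attached as
#'   attribute `ground_truth`.
#' @export
make_participant_table <- function(n_ms = 10L, n_hc = 13L,
                                   predictor_spec = default_predictor_spec(n_ms, n_hc),
                                   family = c("normal", "t"), df = 3,
                                   seed = 1L) {
  family <- match.arg(family)
  if (n_ms < 2L || n_hc < 2L) stop("need at least 2 participants per group")
  set.seed(seed)
  n <- n_ms + n_hc
  group <- factor(rep(c("MS", "HC"), c(n_ms, n_hc)), levels = c("HC", "MS"))
  draw <- function(n, mean, sd) {
    if (family == "normal") rnorm(n, mean, sd)
    else mean + sd * rt(n, df) / sqrt(df / (df - 2))
  }
  out <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                    group = group, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(predictor_spec))) {
    sp <- predictor_spec[i, ]
    out[[sp$name]] <- c(draw(n_ms, sp$mean_ms, sp$sd_ms),
                        draw(n_hc, sp$mean_hc, sp$sd_hc))
  }
  attr(out, "ground_truth") <- predictor_spec
  out
}
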