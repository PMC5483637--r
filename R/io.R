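#' Pipeline run configuration
#'
#' Single declarative container for every tunable of the imaging pipeline
#' and the classification screen, validated on construction. Unknown
#' arguments are rejected (there are no silently ignored settings).
#'
#' @param davis A [davis_params()] object.
#' @param gm_pve_threshold Grey-matter partial volume retention threshold.
#' @param roi_top_fraction Task functional-ROI retention fraction.
#' @param gas_top_fraction,gas_fallback_fraction Gas-challenge ROI
#'   fractions (fallback used when the overlap is too small).
#' @param gas_min_voxels Minimum gas ROI size before escalating.
#' @param fwhm_mm Spatial smoothing kernel FWHM in mm.
#' @param highpass_hz Temporal high-pass cutoff in Hz.
#' @param despike_k Spike-detection threshold in robust SDs.
#' @param averaging_mode `"voxelwise"` (default) or `"roi_mean"` evoked
#'   averaging.
#' @param classification A [classification_config()] object.
#' @param seed Root integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(davis = davis_params(),
                       gm_pve_threshold = 0.80,
                       roi_top_fraction = 0.05,
                       gas_top_fraction = 0.15,
                       gas_fallback_fraction = 0.20,
                       gas_min_voxels = 10L,
                       fwhm_mm = 8,
                       highpass_hz = 0.0039,
                       despike_k = 3,
                       averaging_mode = c("voxelwise", "roi_mean"),
                       classification = classification_config(),
                       seed = 1L) {
  averaging_mode <- match.arg(averaging_mode)
  stopifnot(inherits(davis, "davis_params"),
            inherits(classification, "classification_config"),
            gm_pve_threshold > 0, gm_pve_threshold <= 1,
            roi_top_fraction > 0, roi_top_fraction <= 1,
            gas_top_fraction > 0, gas_top_fraction <= 1,
            gas_fallback_fraction >= gas_top_fraction,
            gas_fallback_fraction <= 1,
            gas_min_voxels >= 1, fwhm_mm >= 0, highpass_hz > 0,
            despike_k > 0)
  structure(list(davis = davis,
                 gm_pve_threshold = gm_pve_threshold,
                 roi_top_fraction = roi_top_fraction,
                 gas_top_fraction = gas_top_fraction,
                 gas_fallback_fraction = gas_fallback_fraction,
                 gas_min_voxels = as.integer(gas_min_voxels),
                 fwhm_mm = fwhm_mm,
                 highpass_hz = highpass_hz,
                 despike_k = despike_k,
                 averaging_mode = averaging_mode,
                 classification = classification,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Deterministic sub-seed derivation
#'
#' Derives a reproducible 31-bit sub-seed from a root seed and a text tag,
#' so that every randomised stage of a run has its own stream while the
#' whole run is reproduced by the single root seed.
#'
#' @param seed Root integer seed.
#' @param tag Character tag naming the consumer.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(tag) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

#' Read a NIfTI volume
#'
#' Loads a 3D or 4D NIfTI-1 file as a plain array plus its voxel geometry.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (array) and `voxel_size_mm` (length 3).
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size_mm = pd[seq_len(min(3L, length(pd)))])
}

#' Write a NIfTI volume
#'
#' @param data 3D/4D array (logical masks are written as integer 0/1).
#' @param path Output path.
#' @param voxel_size_mm Voxel edge lengths in mm, length 3.
#' @return The path, invisibly.
#' @export
save_volume <- function(data, path, voxel_size_mm = c(1, 1, 1)) {
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a participant feature table
#'
#' Reads a delimited participant table, checks for a two-level `group`
#' column, coerces predictor columns to numeric (non-numeric cells become
#' `NA` with a warning) and warns about column names outside the canonical
#' predictor vocabulary (unknown columns are retained).
#'
#' @param path Path to a CSV (or `sep`-delimited) file.
#' @param sep Field separator (default comma).
#' @return Data frame with `group` as a factor.
#' @export
load_table <- function(path, sep = ",") {
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"group" %in% names(tab)) stop("table has no 'group' column")
  g <- factor(tab$group)
  if (nlevels(g) != 2L) {
    stop("'group' must have exactly two levels, found ", nlevels(g))
  }
  tab$group <- g
  known <- c("group", "participant_id", predictor_names())
  unknown <- setdiff(names(tab), known)
  if (length(unknown)) {
    warning("columns outside the canonical predictor vocabulary retained: ",
            paste(unknown, collapse = ", "))
  }
  for (nm in setdiff(names(tab), c("group", "participant_id"))) {
    if (!is.numeric(tab[[nm]])) {
      coerced <- suppressWarnings(as.numeric(tab[[nm]]))
      if (any(is.na(coerced) & !is.na(tab[[nm]]))) {
        warning("non-numeric cells in '", nm, "' set to NA")
      }
      tab[[nm]] <- coerced
    }
  }
  tab
}

#' Write the ranked screen report
#'
#' Writes a classification screen to disk as a ranked CSV plus a JSON
#' record with the full per-predictor results and the run metadata (seed,
#' configuration hash, package version) needed to reproduce it exactly.
#'
#' @param results A `predictor_screen` from [run_full_screen()].
#' @param dir Output directory (created if missing).
#' @param stem File name stem (default `"classification_screen"`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, stem = "classification_screen") {
  stopifnot(inherits(results, "predictor_screen"), nrow(results) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  config <- attr(results, "config")
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  json_path <- file.path(dir, paste0(stem, ".json"))
  write.csv(as.data.frame(results), csv_path, row.names = FALSE)
  payload <- list(
    metadata = list(
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("calfmri")),
      n_boot = config$n_boot,
      n_perm = config$n_perm,
      skipped = as.list(attr(results, "skipped"))
    ),
    results = as.data.frame(results)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
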