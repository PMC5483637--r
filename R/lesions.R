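#' Slice-wise FLAIR hyperintensity mask
#'
#' Flags candidate lesion voxels on a T2-FLAIR volume slice by slice (third
#' array axis): within each slice, a voxel is flagged when its intensity is
#' at or above `mean + z * SD` of the in-brain voxels of that slice. Slice
#' statistics use in-brain voxels only (including the zero background would
#' corrupt the threshold) and the population SD (divide by n). Slices with
#' zero SD flag nothing. Because the threshold is relative, the mask is
#' invariant to per-slice affine intensity rescaling with positive gain.
#'
#' @param flair 3D FLAIR volume.
#' @param brain_mask Logical 3D array of in-brain voxels.
#' @param z Threshold multiplier in slice SD units (default 1.25).
#' @return Logical 3D array of hyperintense voxels.
#' @export
hyperintensity_mask <- function(flair, brain_mask, z = 1.25) {
  stopifnot(length(dim(flair)) == 3L, all(dim(flair) == dim(brain_mask)))
  if (!any(brain_mask)) stop("brain mask is empty")
  out <- array(FALSE, dim(flair))
  for (s in seq_len(dim(flair)[3])) {
    in_brain <- brain_mask[, , s]
    if (!any(in_brain)) next
    v <- flair[, , s][in_brain]
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))  # population SD over the slice
    if (sdev <= 0) next
    sl <- array(FALSE, dim(flair)[1:2])
    sl[in_brain] <- v >= mu + z * sdev
    out[, , s] <- sl
  }
  out
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[ord == 1, , drop = FALSE],
         "18" = off[ord <= 2, , drop = FALSE],
         "26" = off,
         stop("'connectivity' must be 6, 18 or 26"))
}

#' Label connected components of a 3D mask
#'
#' Flood-fill labelling under 6-, 18- or 26-connectivity (face, face+edge,
#' or face+edge+corner neighbours).
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array: 0 outside the mask, component id inside.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  off <- neighbour_offsets(connectivity)
  labels <- array(0L, d)
  seeds <- which(mask)
  next_label <- 0L
  for (seed in seeds) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    stack <- seed
    labels[seed] <- next_label
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(cur, d)
      nb <- sweep(off, 2L, as.integer(co), `+`)
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- next_label
        stack <- c(stack, lin)
      }
    }
  }
  labels
}

#' Count spatially distinct lesions
#'
#' Number of connected components of the lesion mask whose volume reaches
#' `min_volume_mm3` (components below the minimum are excluded from the
#' count, mirroring the rule that a lesion must have at least 3 mm^3 to be
#' counted).
#'
#' @param mask Logical 3D lesion mask.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3, > 0.
#' @param min_volume_mm3 Minimum component volume counted (default 3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer count.
#' @export
count_lesions <- function(mask, voxel_volume_mm3, min_volume_mm3 = 3,
                          connectivity = 26) {
  stopifnot(voxel_volume_mm3 > 0)
  if (!any(mask)) return(0L)
  labels <- label_components(mask, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  sum(sizes * voxel_volume_mm3 >= min_volume_mm3)
}

#' Absolute and relative lesion burden
#'
#' Absolute burden is the masked volume in mm^3; relative burden scales it
#' by the (uncorrected) white-matter volume and reports percent. The
#' distinct count applies the minimum-volume rule of [count_lesions()].
#'
#' @inheritParams count_lesions
#' @param wm_volume_mm3 White-matter volume in mm^3, > 0.
#' @return A list of class `lesion_summary`: `absolute_volume_mm3`,
#'   `relative_volume_pct`, `distinct_count`.
#' @export
lesion_burden <- function(mask, voxel_volume_mm3, wm_volume_mm3,
                          min_volume_mm3 = 3, connectivity = 26) {
  stopifnot(voxel_volume_mm3 > 0)
  if (wm_volume_mm3 <= 0) stop("'wm_volume_mm3' must be positive")
  absolute <- sum(mask) * voxel_volume_mm3
  structure(list(
    absolute_volume_mm3 = absolute,
    relative_volume_pct = 100 * absolute / wm_volume_mm3,
    distinct_count = count_lesions(mask, voxel_volume_mm3, min_volume_mm3,
                                   connectivity)
  ), class = "lesion_summary")
}

#' @export
print.lesion_summary <- function(x, ...) {
  cat(sprintf("Lesion burden: %.1f mm^3 absolute, %.3f%% of white matter, %d distinct lesion(s)\n",
              x$absolute_volume_mm3, x$relative_volume_pct, x$distinct_count))
  invisible(x)
}

#' Dice overlap between two segmentation masks
#'
#' Inter-rater agreement `kappa = 2|A n B| / (|A| + |B|)`; 1 for identical
#' non-empty masks, 0 for disjoint ones. Values above 0.70 are commonly
#' read as excellent agreement (annotation only, not a gate).
#'
#' @param mask_a,mask_b Logical arrays of the same shape; at least one must
#'   be non-empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  na <- sum(mask_a)
  nb <- sum(mask_b)
  if (na + nb == 0) stop("both masks are empty: agreement undefined")
  2 * sum(mask_a & mask_b) / (na + nb)
}
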