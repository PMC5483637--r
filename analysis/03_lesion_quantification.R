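#!/usr/bin/env Rscript

# Step 3: FLAIR lesion burden on synthetic phantoms.
#
# Builds one lesion phantom per simulated MS participant (lesion count and
# sizes drawn per participant), runs the slice-wise hyperintensity
# threshold and the distinct-lesion counting rule, and compares against
# the planted truth. Also demonstrates the Dice inter-rater comparison
# with a rater mask eroded by one voxel per lesion.

suppressPackageStartupMessages(library(calfmri))

seed <- 3407L
dims <- c(32, 32, 8)
wm_volume <- 2e5  # mm^3, a plausible white-matter volume at this scale

draw_spec <- function(n_lesions, rng_seed) {
  set.seed(rng_seed)
  centers <- cbind(sample(9:24, n_lesions), sample(9:24, n_lesions),
                   sample(3:6, n_lesions, replace = TRUE))
  # keep lesions pairwise separated
  keep <- rep(TRUE, n_lesions)
  for (i in seq_len(n_lesions)) {
    for (j in seq_len(i - 1L)) {
      if (keep[j] && sum((centers[i, ] - centers[j, ])^2) < 36) keep[i] <- FALSE
    }
  }
  centers <- centers[keep, , drop = FALSE]
  lapply(seq_len(nrow(centers)), function(i)
    list(center = centers[i, ], voxels = sample(3:12, 1)))
}

rows <- list()
for (p in 1:10) {
  spec <- draw_spec(n_lesions = sample(2:6, 1), rng_seed = seed + p)
  ph <- make_flair_phantom(spec, dims = dims)
  detected <- hyperintensity_mask(ph$flair, ph$brain_mask)
  burden <- lesion_burden(detected, ph$voxel_volume_mm3, wm_volume)
  truth_count <- count_lesions(ph$lesion_mask, ph$voxel_volume_mm3)
  # second rater: misses one voxel of each lesion
  rater_b <- ph$lesion_mask
  labs <- label_components(ph$lesion_mask)
  for (l in seq_len(max(labs))) rater_b[which(labs == l)[1]] <- FALSE
  rows[[p]] <- data.frame(
    participant = sprintf("MS%02d", p),
    planted = truth_count,
    detected_count = burden$distinct_count,
    absolute_mm3 = burden$absolute_volume_mm3,
    relative_pct = burden$relative_volume_pct,
    dice_raters = dice(ph$lesion_mask, rater_b))
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/lesion_metrics.csv", row.names = FALSE)

cat(sprintf("Lesion recovery: %d/%d phantoms counted exactly\n",
            sum(out$planted == out$detected_count), nrow(out)))
cat(sprintf("Mean inter-rater Dice with 1-voxel erosion: %.3f\n",
            mean(out$dice_raters)))
print(out, row.names = FALSE)
cat("Wrote results/lesion_metrics.csv\n")
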