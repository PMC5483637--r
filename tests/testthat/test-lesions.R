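test_that("hyperintensity threshold works slice-wise on in-brain voxels", {
  dims <- c(10, 10, 2)
  brain <- array(TRUE, dims)
  flair <- array(100, dims)
  # constant slice: SD = 0, nothing flagged
  expect_false(any(hyperintensity_mask(flair, brain)))
  # 99 voxels at 100 and one at 200: mean 101, population SD sqrt(99),
  # threshold ~113.4 -> exactly the outlier flagged
  flair[5, 5, 1] <- 200
  m <- hyperintensity_mask(flair, brain)
  expect_identical(which(m), 45L)   # linear index of [5, 5, 1]
  expect_equal(sum(m), 1L)
  # second slice with a different baseline but the same relative outlier
  flair[, , 2] <- 250
  flair[5, 5, 2] <- 500
  m2 <- hyperintensity_mask(flair, brain)
  expect_equal(sum(m2[, , 2]), 1L)
  expect_true(m2[5, 5, 2])
  expect_error(hyperintensity_mask(flair, array(FALSE, dims)), "empty")
})

test_that("hyperintensity mask is invariant to per-slice affine rescaling", {
  dims <- c(8, 8, 3)
  set.seed(4)
  flair <- array(rnorm(prod(dims), 100, 10), dims)
  brain <- array(TRUE, dims)
  ref <- hyperintensity_mask(flair, brain)
  scaled <- flair
  gains <- c(2.5, 0.3, 7); offs <- c(-20, 55, 3)
  for (s in 1:3) scaled[, , s] <- gains[s] * flair[, , s] + offs[s]
  expect_identical(hyperintensity_mask(scaled, brain), ref)
})

test_that("lesion counting respects connectivity and minimum volume", {
  dims <- c(8, 8, 4)
  mask <- array(FALSE, dims)
  mask[1:2, 1:2, 1:2] <- TRUE   # 8-voxel cube
  mask[6:7, 6:7, 3:4] <- TRUE   # second separated cube
  expect_equal(count_lesions(mask, 1), 2L)
  # a 2-voxel blob at 1 mm^3 per voxel stays below the 3 mm^3 rule
  small <- array(FALSE, dims); small[4, 4, 1] <- TRUE; small[5, 4, 1] <- TRUE
  expect_equal(count_lesions(small, 1), 0L)
  # but counts once voxels are large enough
  expect_equal(count_lesions(small, 2), 1L)
  # corner-touching blobs merge under 26-connectivity, split under 6
  diag2 <- array(FALSE, dims)
  diag2[1:2, 1:2, 1] <- TRUE
  diag2[3:4, 3:4, 2] <- TRUE
  expect_equal(count_lesions(diag2, 1, connectivity = 26), 1L)
  expect_equal(count_lesions(diag2, 1, connectivity = 6), 2L)
  expect_equal(count_lesions(array(FALSE, dims), 1), 0L)
})

test_that("lesion count is monotone non-increasing in the minimum volume", {
  set.seed(9)
  mask <- array(runif(10 * 10 * 5) > 0.8, c(10, 10, 5))
  counts <- vapply(c(0.5, 1, 2, 3, 5, 8),
                   function(v) count_lesions(mask, 1, min_volume_mm3 = v),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("lesion burden combines absolute and relative scales", {
  dims <- c(20, 20, 5)
  mask <- array(FALSE, dims)
  mask[1:10, 1:10, 1:5] <- TRUE   # 500 voxels
  b <- lesion_burden(mask, 1, wm_volume_mm3 = 5e5)
  expect_equal(b$absolute_volume_mm3, 500)
  expect_equal(b$relative_volume_pct, 0.1)
  empty <- lesion_burden(array(FALSE, dims), 1, 1000)
  expect_equal(empty$absolute_volume_mm3, 0)
  expect_equal(empty$relative_volume_pct, 0)
  expect_equal(empty$distinct_count, 0L)
  # anisotropic voxel volume: 3000 voxels at 1.0125 mm^3
  big <- array(FALSE, c(30, 10, 10)); big[seq_len(3000)] <- TRUE
  expect_equal(lesion_burden(big, 1.0125, 1e6)$absolute_volume_mm3, 3037.5)
  expect_error(lesion_burden(mask, 1, 0), "positive")
})

test_that("dice agreement behaves as a proper overlap score", {
  a <- array(FALSE, c(6, 6, 3)); a[1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(6, 6, 3)); b[20:29] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100 with overlap 80
  A <- array(FALSE, c(20, 20, 1)); A[1:100] <- TRUE
  B <- array(FALSE, c(20, 20, 1)); B[21:120] <- TRUE
  expect_equal(dice(A, B), 0.8)
  expect_equal(dice(A, B), dice(B, A))
  expect_error(dice(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))),
               "empty")
})

test_that("phantom lesions are recovered exactly by the full chain", {
  ph <- make_flair_phantom(phantom_spec())
  detected <- hyperintensity_mask(ph$flair, ph$brain_mask)
  # the detected mask is exactly the planted truth (decoy included)
  expect_identical(detected, ph$lesion_mask)
  # five lesions reach 3 mm^3; the 2-voxel decoy does not
  expect_equal(count_lesions(detected, ph$voxel_volume_mm3), 5L)
  b <- lesion_burden(detected, ph$voxel_volume_mm3, wm_volume_mm3 = 2e5)
  expect_equal(b$absolute_volume_mm3, sum(vapply(phantom_spec(),
                                                 `[[`, numeric(1), "voxels")))
  expect_equal(dice(detected, ph$lesion_mask), 1)
  # a rater mask missing one voxel gives the exact set-arithmetic Dice
  n <- sum(ph$lesion_mask)
  rater <- ph$lesion_mask
  rater[which(rater)[1]] <- FALSE
  expect_equal(dice(ph$lesion_mask, rater), 2 * (n - 1) / (2 * n - 1))
})
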