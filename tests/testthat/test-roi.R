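test_that("grey-matter mask applies an inclusive threshold", {
  pve <- array(c(0.80, 0.79, 1, 0, 0.5, 0.81, 0.2, 0.9), c(2, 2, 2))
  m <- grey_matter_mask(pve)
  expect_identical(c(m), c(pve) >= 0.80)
  expect_true(m[1, 1, 1])     # exactly at threshold: retained
  expect_false(m[2, 1, 1])    # just below: excluded
  expect_false(any(grey_matter_mask(array(0, c(2, 2, 2)))))
  expect_error(grey_matter_mask(array(1.5, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("functional ROI is the overlap of the top t-value sets", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  # top-50 sets sharing exactly voxels 31..50
  tb <- array(as.numeric(1000:1), dims)  # voxel 1 highest: top 50 = 1..50
  tcv <- numeric(1000)
  tcv[31:80] <- 1000 - (0:49)            # voxels 31..80 get the top values
  set.seed(1)
  tcv[-(31:80)] <- sample(seq_len(950))  # the rest, strictly lower
  tc <- array(tcv, dims)
  roi <- functional_roi(tb, tc, mask, top_fraction = 0.05)
  expect_equal(attr(roi, "n_voxels"), 20)
  expect_identical(which(roi), 31:50)
  # identical maps: self-overlap of ceiling(0.05 * N) voxels
  roi2 <- functional_roi(tb, tb, mask, top_fraction = 0.05)
  expect_equal(attr(roi2, "n_voxels"), 50)
  # disjoint top sets: explicit empty-ROI failure
  expect_error(functional_roi(tb, array(as.numeric(1:1000), dims), mask, 0.01),
               "empty")
  # always a subset of the structural mask
  set.seed(7)
  m2 <- array(runif(1000) > 0.5, dims)
  r3 <- functional_roi(array(rnorm(1000), dims), array(rnorm(1000), dims),
                       m2, 0.2)
  expect_true(all(which(r3) %in% which(m2)))
})

test_that("gas summary recovers the calibration constant exactly", {
  dims <- c(6, 6, 3)
  mask <- array(TRUE, dims)
  g <- make_gas_run(m = 0.05, delta_cbf_hc = 1.5, dims = dims, snr = Inf)
  gs <- gas_roi_and_summary(g, mask)
  expect_equal(gs$m, 0.05, tolerance = 1e-6)
  expect_equal(gs$delta_cbf_hc, 1.5, tolerance = 1e-6)
  # uniform +2% BOLD at doubled CBF corresponds to M of 4.24%
  m424 <- 0.02 / (1 - 2^(-0.92))
  g2 <- make_gas_run(m = m424, delta_cbf_hc = 1.0, dims = dims, snr = Inf)
  gs2 <- gas_roi_and_summary(g2, mask)
  expect_equal(gs2$delta_bold_hc, 0.02, tolerance = 1e-8)
  expect_equal(gs2$m_percent, 4.24, tolerance = 1e-2)
})

test_that("gas ROI escalates the retention fraction when too small", {
  dims <- c(6, 6, 3)
  mask <- array(TRUE, dims)
  g <- make_gas_run(m = 0.05, delta_cbf_hc = 1.5, dims = dims, snr = Inf)
  gs <- gas_roi_and_summary(g, mask, min_voxels = 200L)
  expect_equal(gs$top_fraction_used, 0.20)
  expect_error(gas_roi_and_summary(g, mask, baseline_s = 100), "4 min")
})

test_that("the discarded hypercapnia transition cannot affect the summary", {
  dims <- c(6, 6, 3)
  mask <- array(TRUE, dims)
  g <- make_gas_run(m = 0.05, delta_cbf_hc = 1.5, dims = dims, snr = Inf)
  ref <- gas_roi_and_summary(g, mask)
  # trash the first two minutes after gas onset (times 248..352 s)
  bad <- which((seq_len(dim(g$bold_echo)[4]) - 1) * 4 >= 248 &
                 (seq_len(dim(g$bold_echo)[4]) - 1) * 4 <= 352)
  set.seed(1)
  g$bold_echo[, , , bad] <- 5000 * runif(length(g$bold_echo[, , , bad]))
  g$perfusion_echo[, , , bad] <- 5000 * runif(length(g$perfusion_echo[, , , bad]))
  out <- gas_roi_and_summary(g, mask)
  expect_equal(out$m, ref$m, tolerance = 1e-8)
  expect_equal(out$bold_0, ref$bold_0, tolerance = 1e-8)
  expect_equal(out$cbf_hc, ref$cbf_hc, tolerance = 1e-8)
})

test_that("evoked measures match the closed form on uniform maps", {
  dims <- c(4, 4, 2)
  roi <- array(TRUE, dims)
  db <- array(0.01, dims); dc <- array(0.5, dims)
  ev <- evoked_measures(db, dc, roi, m = 0.05)
  # 100 * ((1 - 0.2)^(1/1.3) * 1.5^(1 - 0.38/1.3) - 1), evaluated directly
  expect_equal(ev$ve_cmro2, 100 * (0.8^(1 / 1.3) * 1.5^(1 - 0.38 / 1.3) - 1),
               tolerance = 1e-9)
  expect_equal(ev$ve_bold, 1.0)
  expect_equal(ev$ve_cbf, 50.0)
  # uniform maps: voxelwise and roi-mean averaging agree exactly
  ev2 <- evoked_measures(db, dc, roi, m = 0.05, mode = "roi_mean")
  expect_equal(ev$ve_cmro2, ev2$ve_cmro2, tolerance = 1e-12)
  expect_equal(ev$ve_n, ev2$ve_n, tolerance = 1e-12)
})

test_that("voxelwise and roi-mean averaging differ on heterogeneous maps", {
  dims <- c(2, 1, 1)
  roi <- array(TRUE, dims)
  db <- array(c(0.005, 0.02), dims)
  dc <- array(c(0.3, 1.2), dims)
  m <- 0.05
  vox <- evoked_measures(db, dc, roi, m, mode = "voxelwise")
  agg <- evoked_measures(db, dc, roi, m, mode = "roi_mean")
  # hand-computed two-voxel expectations
  dm1 <- compute_delta_cmro2(0.005, 0.3, m)
  dm2 <- compute_delta_cmro2(0.02, 1.2, m)
  expect_equal(vox$ve_cmro2, 100 * mean(c(dm1, dm2)), tolerance = 1e-12)
  expect_equal(vox$ve_n, mean(c(0.3 / dm1, 1.2 / dm2)), tolerance = 1e-12)
  expect_equal(agg$ve_cmro2,
               100 * compute_delta_cmro2(mean(db), mean(dc), m),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(vox$ve_cmro2, agg$ve_cmro2)))
  # a single-voxel ROI makes the modes coincide
  roi1 <- array(c(TRUE, FALSE), dims)
  expect_equal(evoked_measures(db, dc, roi1, m)$ve_cmro2,
               evoked_measures(db, dc, roi1, m, mode = "roi_mean")$ve_cmro2)
})

test_that("evoked measures skip ceiling-violating voxels with a count", {
  dims <- c(3, 1, 1)
  roi <- array(TRUE, dims)
  db <- array(c(0.01, 0.06, 0.01), dims)   # middle voxel exceeds M = 0.05
  dc <- array(0.5, dims)
  ev <- evoked_measures(db, dc, roi, 0.05)
  expect_equal(ev$n_skipped, 1L)
  expect_equal(ev$roi_voxels, 3L)
  db_bad <- array(0.06, dims)
  expect_error(evoked_measures(db_bad, dc, roi, 0.05), "all ROI voxels")
})
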