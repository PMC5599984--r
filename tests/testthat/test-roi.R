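test_that("in-plane erosion of a 5x5 square leaves its 3x3 core and kills 1-voxel-thin masks", {
  mask <- box_mask(c(9, 9, 3), c(3, 3, 2), c(7, 7, 2))
  er <- erode_mask(mask, roi_policy())
  expected <- array(0L, dim = c(9, 9, 3))
  expected[4:6, 4:6, 2] <- 1L
  expect_identical(er$voxels, expected)

  thin <- box_mask(c(9, 9, 3), c(3, 5, 1), c(7, 5, 3)) # 1 voxel wide in-plane
  expect_identical(sum(erode_mask(thin)$voxels), 0L)

  # through-plane structure is untouched in in-plane mode: a single-slice
  # sheet survives where a full-3D element would erase it
  sheet <- box_mask(c(9, 9, 3), c(2, 2, 2), c(8, 8, 2))
  expect_gt(sum(erode_mask(sheet)$voxels), 0)
  expect_identical(sum(erode_mask(sheet, roi_policy(erosion_mode = "full-3D"))$voxels), 0L)
})

test_that("erosion matches the brute-force neighbourhood oracle in both modes", {
  withr::local_seed(21)
  for (mode in c("in-plane-2D", "full-3D")) {
    for (rep in 1:3) {
      vox <- array(0L, dim = c(16, 14, 8))
      vox[sample(length(vox), 500)] <- sample(1:2, 500, replace = TRUE)
      # add a solid blob so erosion is not trivially empty
      vox[4:10, 4:10, 3:6] <- 1L
      mask <- label_mask(vox)
      er <- erode_mask(mask, roi_policy(erosion_mode = mode))
      expect_identical(er$voxels, oracle_erode(vox, mode = mode))
      expect_true(all(er$voxels == 0L | er$voxels == vox)) # output subset of input
      expect_lt(sum(er$voxels > 0), sum(vox > 0))          # strict when boundary non-empty
    }
  }
})

test_that("in-plane erosion agrees with EBImage framewise erosion", {
  skip_if_not_installed("EBImage")
  withr::local_seed(5)
  vox <- array(0L, dim = c(20, 20, 5))
  vox[sample(length(vox), 400)] <- 1L
  vox[6:14, 6:14, 2:4] <- 1L
  er <- erode_mask(label_mask(vox), roi_policy())
  kern <- EBImage::makeBrush(3, shape = "box")
  ref <- array(0L, dim = dim(vox))
  for (k in seq_len(dim(vox)[3])) {
    ref[, , k] <- as.integer(EBImage::erode(vox[, , k], kern))
  }
  expect_identical(er$voxels, ref)
})

test_that("CSF exclusion removes voxels strictly above the cutoff and invalid fits", {
  vals <- array(NA_real_, dim = c(5, 1, 1))
  vals[, 1, 1] <- c(120, 170, 171, 2000, NA)
  t2m <- t2_map_from_array(vals)
  mask <- label_mask(array(c(1L, 1L, 1L, 1L, 1L), dim = c(5, 1, 1)))
  out <- exclude_csf(mask, t2m, roi_policy())
  expect_identical(as.vector(out$voxels), c(1L, 1L, 0L, 0L, 0L))
  expect_identical(unname(attr(out, "n_excluded_csf")["1"]), 2L)
  expect_identical(unname(attr(out, "n_invalid")["1"]), 1L)

  # all below threshold: unchanged
  low <- t2_map_from_array(array(c(100, 110, 120, 130, 140), dim = c(5, 1, 1)))
  expect_identical(exclude_csf(mask, low)$voxels, mask$voxels)
})

test_that("ROI summary pools voxels with n-1 SD and flags small ROIs", {
  vals <- array(NA_real_, dim = c(2, 1, 1))
  vals[, 1, 1] <- c(100, 120)
  t2m <- t2_map_from_array(vals)
  mask <- label_mask(array(1L, dim = c(2, 1, 1)))
  s <- summarize_roi(mask, t2m, roi_policy(min_voxels = 2))
  expect_equal(s$mean_t2_ms, 110)
  expect_equal(s$sd_t2_ms, sqrt(200), tolerance = 1e-12) # 14.142...
  expect_identical(s$n_voxels, 2L)
  expect_true(s$reliable)
  expect_false(summarize_roi(mask, t2m, roi_policy(min_voxels = 20))$reliable)

  empty <- label_mask(array(0L, dim = c(2, 1, 1)))
  expect_error(summarize_roi(empty, t2m), class = "hippot2_error_empty_roi")
})

test_that("a uniform noiseless hippocampus summarizes to its true T2 exactly", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, seed = 3))
  t2m <- fit_t2_map(ph$acq)
  m <- measure_hippocampal_t2(hippocampus_mask(ph$labels), t2m)
  expect_equal(m$mean_t2_ms, c(115, 115))
  expect_equal(m$sd_t2_ms, c(0, 0))
})

test_that("with noise the full chain recovers true T2 within 1.5 msec at SNR 50", {
  ph <- generate_phantom(small_spec(seed = 9)) # default snr = 50
  t2m <- fit_t2_map(ph$acq)
  m <- measure_hippocampal_t2(hippocampus_mask(ph$labels), t2m)
  expect_true(all(m$n_voxels >= 200))
  expect_true(all(abs(m$mean_t2_ms - 115) < 1.5))
})

test_that("every retained voxel belongs to the original segmentation and counts are monotone", {
  ph <- generate_phantom(small_spec(seed = 13))
  t2m <- fit_t2_map(ph$acq)
  seg <- hippocampus_mask(ph$labels, dilate = 1)
  er <- erode_mask(seg)
  cl <- exclude_csf(er, t2m)
  expect_lte(sum(cl$voxels > 0), sum(er$voxels > 0))
  expect_lte(sum(er$voxels > 0), sum(seg$voxels > 0))
  expect_true(all(cl$voxels == 0L | cl$voxels == seg$voxels))
})

test_that("ground-truth CSF voxels inside a generous segmentation are all excluded", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, seed = 4))
  t2m <- fit_t2_map(ph$acq)
  seg <- hippocampus_mask(ph$labels, dilate = 1)
  csf <- ph$labels$voxels == tissue_labels()["csf"]
  expect_gt(sum(seg$voxels > 0 & csf), 0) # the segmentation does overreach into CSF
  cleaned <- exclude_csf(seg, t2m)
  expect_identical(sum(cleaned$voxels > 0 & csf), 0L)
})

test_that("slice profile is AP-ordered, matches truth, and its weighted mean equals the pooled mean", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, seed = 6))
  t2m <- fit_t2_map(ph$acq)
  seg <- hippocampus_mask(ph$labels)
  prof <- slice_profile(seg, t2m, label = 1L)
  expect_true(all(prof$mean_t2_ms == 115)) # flat for a uniform phantom
  expect_true(all(diff(prof$y_mm) < 0))    # anterior (+y) first

  # anterior-elevated hippocampus: step profile recovered
  t2v <- ph$t2_truth$voxels
  front <- prof$slice_index[seq_len(floor(nrow(prof) / 2))] # anterior half
  sel <- seg$voxels == 1L & slice.index(t2v, 3) %in% (front + 1L)
  t2v[sel] <- 125
  t2m2 <- t2_map_from_array(t2v, ph$t2_truth$affine)
  t2m2$valid <- t2m$valid
  t2m2$t2$voxels[!t2m$valid] <- NA_real_
  prof2 <- slice_profile(seg, t2m2, label = 1L)
  expect_true(all(prof2$mean_t2_ms[prof2$slice_index %in% front] == 125))
  expect_true(all(prof2$mean_t2_ms[!prof2$slice_index %in% front] == 115))

  pooled <- summarize_roi(seg, t2m2)
  expect_equal(sum(prof2$mean_t2_ms * prof2$n_voxels) / sum(prof2$n_voxels),
               pooled$mean_t2_ms[pooled$label == 1L], tolerance = 1e-12)
})
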