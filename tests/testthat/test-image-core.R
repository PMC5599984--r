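test_that("NIfTI write/read round-trips voxels, affine and datatype", {
  # float32-representable affine entries so the sform round-trips exactly
  aff <- diag(c(0.5, 0.5, 4, 1))
  aff[1:3, 4] <- c(-16, -16, -32)
  img <- volumetric_image(array(rnorm(10 * 10 * 10), dim = c(10, 10, 10)), aff)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  read_back <- read_nifti(write_nifti(img, path))
  expect_identical(read_back$voxels, img$voxels)
  expect_identical(read_back$affine, img$affine)

  mask <- label_mask(array(sample(0:2, 125, replace = TRUE), dim = c(5, 5, 5)), aff)
  mpath <- withr::local_tempfile(fileext = ".nii")
  mread <- read_nifti(write_nifti(mask, mpath), label = TRUE)
  expect_identical(mread$voxels, mask$voxels)
  expect_true(is.integer(mread$voxels))
})

test_that("a 4-D volume with singleton trailing dimension is squeezed to 3-D", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  arr4 <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6, 1))
  RNifti::writeNifti(RNifti::asNifti(arr4), path)
  img <- read_nifti(path)
  expect_length(dim(img$voxels), 3L)
  expect_identical(dim(img$voxels), c(4L, 5L, 6L))
  expect_equal(img$voxels, array(arr4, dim = c(4, 5, 6)))
})

test_that("unreadable inputs raise classed errors", {
  bogus <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not a nifti file", bogus)
  expect_error(read_nifti(bogus), class = "hippot2_error_bad_nifti")
  expect_error(read_nifti(file.path(tempdir(), "no-such-file.nii")),
               class = "hippot2_error_missing_file")
  expect_error(volumetric_image(array(1, dim = c(2, 2, 2, 3))),
               class = "hippot2_error_bad_image")
  expect_error(volumetric_image(array(1, dim = c(3, 3, 3)), matrix(0, 4, 4)),
               class = "hippot2_error_bad_affine")
})

test_that("rigid transform text files round-trip and non-rigid matrices are rejected", {
  tr <- rigid_about(c(1, 2, 3), 0.3, translation = c(1.5, -2, 0.25))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  expect_equal(read_transform(path), tr, tolerance = 1e-12)

  scaled <- diag(c(2, 1, 1, 1))
  expect_error(validate_rigid(scaled), class = "hippot2_error_bad_transform")
  reflect <- diag(c(-1, 1, 1, 1))
  expect_error(validate_rigid(reflect), class = "hippot2_error_bad_transform")
  expect_silent(validate_rigid(tr))
})

test_that("resampling with identity transform on identical grids is the identity", {
  mask <- box_mask(c(12, 12, 6), c(4, 4, 2), c(8, 8, 4), label = 2L)
  ref <- volumetric_image(array(0, dim = c(12, 12, 6)))
  out <- resample_mask(mask, diag(4), ref)
  expect_identical(out$voxels, mask$voxels)
})

test_that("a one-voxel world translation shifts labels by one voxel and conserves volume", {
  mask <- box_mask(c(16, 16, 8), c(5, 5, 3), c(10, 10, 5))
  ref <- volumetric_image(array(0, dim = c(16, 16, 8)))
  tr <- diag(4)
  tr[1, 4] <- 1 # +1 mm = +1 voxel on this unit grid
  out <- resample_mask(mask, tr, ref)
  expect_identical(sum(out$voxels), sum(mask$voxels))
  shifted <- array(0L, dim = dim(mask$voxels))
  shifted[6:11, 5:10, 3:5] <- 1L
  expect_identical(out$voxels, shifted)
})

test_that("a transform moving the mask outside the reference yields an empty mask with a warning", {
  mask <- box_mask(c(10, 10, 5), c(3, 3, 2), c(6, 6, 3))
  ref <- volumetric_image(array(0, dim = c(10, 10, 5)))
  tr <- diag(4)
  tr[1, 4] <- 1000
  expect_warning(out <- resample_mask(mask, tr, ref), "overlap")
  expect_identical(sum(out$voxels), 0L)
})

test_that("resampling matches the brute-force pull-back oracle under rotation + translation", {
  withr::local_seed(11)
  for (rep in 1:3) {
    d <- c(14L, 12L, 10L)
    vox <- array(0L, dim = d)
    vox[sample(length(vox), 150)] <- sample(1:2, 150, replace = TRUE)
    aff <- diag(c(1, 1, 2, 1))
    aff[1:3, 4] <- c(-7, -6, -10)
    mask <- label_mask(vox, aff)
    ref <- volumetric_image(array(0, dim = d), aff)
    tr <- rigid_about(rnorm(3), runif(1, -0.4, 0.4), translation = runif(3, -2, 2))
    out <- resample_mask(mask, tr, ref)
    expect_identical(out$voxels, oracle_resample(mask, tr, ref))
    # nearest-neighbour pull-back can never invent labels
    expect_true(all(unique(as.vector(out$voxels)) %in%
                      c(0L, unique(as.vector(vox)))))
  }
})

test_that("labeled volume is conserved within a boundary shell under rigid motion between equal-resolution grids", {
  mask <- box_mask(c(20, 20, 10), c(6, 6, 3), c(14, 14, 7))
  ref <- volumetric_image(array(0, dim = c(20, 20, 10)))
  tr <- rigid_about(c(0, 0, 1), 0.15, translation = c(0.4, -0.6, 0.2))
  out <- resample_mask(mask, tr, ref)
  n_in <- sum(mask$voxels > 0)
  # one-voxel shell around the transformed box
  shell <- sum(erode_mask(mask, roi_policy(erosion_mode = "full-3D"))$voxels > 0)
  expect_gt(sum(out$voxels > 0), shell)
  expect_lt(abs(sum(out$voxels > 0) - n_in), n_in - shell + 1)
})
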