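#' Volumetric image: a 3-D voxel grid with a voxel-to-world affine
#'
#' The carrier for all spatial data in the package: structural images,
#' dual-echo images, T2 maps and label masks all share this contract. Voxel
#' indices are 0-based and world coordinates are in mm following the NIfTI
#' affine convention (RAS+ assumed): the world position of voxel
#' `(i, j, k)` (0-based) is `affine %*% c(i, j, k, 1)`.
#'
#' @param voxels A 3-D numeric array. A 4-D array with a singleton trailing
#'   dimension is squeezed to 3-D.
#' @param affine A 4x4 invertible voxel-index-to-world-mm matrix.
#' @return An object of class `vol_img` with fields `voxels` and `affine`.
#' @export
volumetric_image <- function(voxels, affine = diag(4)) {
  voxels <- squeeze_to_3d(voxels)
  affine <- validate_affine(affine)
  if (any(dim(voxels) < 1L)) {
    ht2_abort("image must have extent >= 1 on every axis", "hippot2_error_bad_image")
  }
  structure(list(voxels = voxels, affine = affine), class = "vol_img")
}

#' Label mask: a volumetric image of non-negative integer labels
#'
#' Shares the grid contract of [volumetric_image()]. Label 0 is background;
#' by convention 1 = left hippocampus and 2 = right hippocampus (see
#' [hippocampus_labels()]).
#'
#' @inheritParams volumetric_image
#' @return An object of class `label_mask` (inherits `vol_img`).
#' @export
label_mask <- function(voxels, affine = diag(4)) {
  voxels <- squeeze_to_3d(voxels)
  if (any(voxels < 0, na.rm = TRUE) || any(voxels != round(voxels), na.rm = TRUE)) {
    ht2_abort("mask labels must be non-negative integers", "hippot2_error_bad_mask")
  }
  storage.mode(voxels) <- "integer"
  img <- volumetric_image(voxels, affine)
  class(img) <- c("label_mask", class(img))
  img
}

#' Conventional hippocampal label table
#'
#' @return Named integer vector mapping structure names to mask labels.
#' @export
hippocampus_labels <- function() c(left = 1L, right = 2L)

squeeze_to_3d <- function(voxels) {
  d <- dim(voxels)
  if (is.null(d)) ht2_abort("voxels must be an array", "hippot2_error_bad_image")
  if (length(d) > 3L) {
    if (any(d[-(1:3)] != 1L)) {
      ht2_abort(
        sprintf("image has %d non-singleton dimensions; at most 3 supported",
                sum(d != 1L)),
        "hippot2_error_bad_image")
    }
    voxels <- array(voxels, dim = d[1:3])
  }
  if (length(dim(voxels)) == 2L) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  voxels
}

validate_affine <- function(affine) {
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L))) {
    ht2_abort("affine must be a 4x4 matrix", "hippot2_error_bad_affine")
  }
  if (abs(det(affine)) < .Machine$double.eps * 1e4) {
    ht2_abort("affine must be invertible", "hippot2_error_bad_affine")
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) {
    ht2_abort("voxel sizes derived from the affine must be positive",
              "hippot2_error_bad_affine")
  }
  affine
}

#' Voxel dimensions in mm derived from the affine
#'
#' @param img A `vol_img`.
#' @return Length-3 numeric vector: the mm length of each voxel axis.
#' @export
voxel_size <- function(img) {
  sqrt(colSums(img$affine[1:3, 1:3]^2))
}

#' Volume of one voxel in mm^3
#' @param img A `vol_img`.
#' @return Scalar mm^3 (affine determinant magnitude).
#' @export
voxel_volume_mm3 <- function(img) abs(det(img$affine[1:3, 1:3]))

#' @export
print.vol_img <- function(x, ...) {
  d <- dim(x$voxels)
  vs <- voxel_size(x)
  cat(sprintf("<%s> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @export
dim.vol_img <- function(x) dim(x$voxels)

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volumetric_image()]. 4-D inputs with
#' a singleton trailing dimension are squeezed to 3-D; more than three
#' non-singleton dimensions are an error.
#'
#' @param path Path to a NIfTI-1 file.
#' @param label If `TRUE`, return a [label_mask()] (voxels coerced to
#'   integer labels).
#' @return A `vol_img` (or `label_mask`).
#' @export
read_nifti <- function(path, label = FALSE) {
  if (!file.exists(path)) {
    ht2_abort(sprintf("file not found: %s", path), "hippot2_error_missing_file")
  }
  # a malformed file warns before it errors; fold both into one condition
  deferred <- character()
  nii <- withCallingHandlers(
    tryCatch(
      RNifti::readNifti(path),
      error = function(e) {
        ht2_abort(sprintf("not a readable NIfTI-1 volume: %s (%s)",
                          path, conditionMessage(e)),
                  "hippot2_error_bad_nifti")
      }),
    warning = function(w) {
      deferred <<- c(deferred, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (msg in deferred) warn(msg)
  aff <- RNifti::xform(nii)
  attributes(aff) <- list(dim = dim(aff))
  vox <- as.array(nii)
  attributes(vox) <- list(dim = dim(vox))
  if (label) label_mask(vox, aff) else volumetric_image(vox, aff)
}

#' Write a NIfTI-1 volume
#'
#' Label masks are written as int16 so that labels round-trip exactly;
#' other images default to float64 (`datatype = "double"`) so voxel values
#' round-trip bit-exactly. The affine is stored in the sform (code 2). Note
#' NIfTI-1 stores the sform rows as float32, so affines round-trip exactly
#' only when their entries are float32-representable.
#'
#' @param img A `vol_img` or `label_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype string passed to [RNifti::asNifti()];
#'   defaults to `"int16"` for label masks and `"double"` otherwise.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = NULL) {
  stopifnot(inherits(img, "vol_img"))
  if (!dir.exists(dirname(path))) {
    ht2_abort(sprintf("directory does not exist: %s", dirname(path)),
              "hippot2_error_unwritable")
  }
  if (is.null(datatype)) {
    datatype <- if (inherits(img, "label_mask")) "int16" else "double"
  }
  nii <- RNifti::asNifti(img$voxels, datatype = datatype)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read or write a 4x4 world-to-world rigid transform as plain text
#'
#' The on-disk dialect is the one emitted by common registration tools:
#' four whitespace-separated rows of four numbers, row-major, mapping world
#' mm in the source frame to world mm in the target frame.
#'
#' @param path Path to the text file.
#' @return `read_transform`: a 4x4 matrix. `write_transform`: `path`,
#'   invisibly.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) {
    ht2_abort(sprintf("transform file not found: %s", path),
              "hippot2_error_missing_file")
  }
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16L) {
    ht2_abort(sprintf("expected 16 numbers in transform file, got %d",
                      length(vals)), "hippot2_error_bad_transform")
  }
  matrix(vals, nrow = 4L, byrow = TRUE)
}

#' @rdname read_transform
#' @param transform A 4x4 matrix.
#' @export
write_transform <- function(transform, path) {
  stopifnot(is.matrix(transform), all(dim(transform) == 4L))
  writeLines(apply(transform, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Check that a 4x4 matrix is a rigid (rotation + translation) transform
#'
#' @param transform 4x4 matrix.
#' @param tol Orthonormality tolerance on the 3x3 block (default 1e-6).
#' @return `transform`, invisibly; errors if non-rigid.
#' @export
validate_rigid <- function(transform, tol = 1e-6) {
  if (!is.matrix(transform) || any(dim(transform) != 4L)) {
    ht2_abort("transform must be a 4x4 matrix", "hippot2_error_bad_transform")
  }
  R <- transform[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    ht2_abort("transform is not rigid: 3x3 block must be orthonormal with determinant +1",
              "hippot2_error_bad_transform")
  }
  if (max(abs(transform[4, ] - c(0, 0, 0, 1))) > tol) {
    ht2_abort("last row of a rigid transform must be (0, 0, 0, 1)",
              "hippot2_error_bad_transform")
  }
  invisible(transform)
}

#' Resample a label mask onto a reference grid through a rigid transform
#'
#' Nearest-neighbour pull-back: for each reference voxel, its world-mm
#' center is mapped through the inverse of `transform` (which maps the
#' mask's world frame to the reference's world frame) into the mask's world
#' frame, then through the mask's inverse affine to a voxel index, and the
#' nearest source voxel's label is taken. No interpolation, so no
#' fractional labels: the output label set is a subset of the input's.
#'
#' @param mask A `label_mask` on its native (e.g. structural) grid.
#' @param transform 4x4 rigid matrix mapping mask world mm to reference
#'   world mm (registration-tool convention; see `invert`).
#' @param reference A `vol_img` providing the target grid and affine
#'   (e.g. the T2 map).
#' @param invert If `TRUE`, `transform` is interpreted in the opposite
#'   direction (reference world to mask world) and inverted before use.
#' @return A `label_mask` on the reference grid. If no transformed label
#'   lands inside the reference field of view a warning is emitted and the
#'   mask is empty.
#' @export
resample_mask <- function(mask, transform = diag(4), reference, invert = FALSE) {
  stopifnot(inherits(mask, "label_mask"), inherits(reference, "vol_img"))
  validate_rigid(transform)
  if (invert) transform <- solve(transform)
  # composite map: reference voxel index -> source voxel index (0-based)
  M <- solve(mask$affine) %*% solve(transform) %*% reference$affine
  d_ref <- dim(reference$voxels)
  d_src <- dim(mask$voxels)
  idx <- cbind(
    as.matrix(expand.grid(i = 0:(d_ref[1] - 1L),
                          j = 0:(d_ref[2] - 1L),
                          k = 0:(d_ref[3] - 1L))),
    1)
  src <- idx %*% t(M)          # N x 4, 0-based source indices
  si <- round(src[, 1:3]) + 1  # 1-based
  inb <- si[, 1] >= 1 & si[, 1] <= d_src[1] &
         si[, 2] >= 1 & si[, 2] <= d_src[2] &
         si[, 3] >= 1 & si[, 3] <= d_src[3]
  out <- integer(nrow(idx))
  lin <- si[inb, 1] + (si[inb, 2] - 1L) * d_src[1] +
    (si[inb, 3] - 1L) * d_src[1] * d_src[2]
  out[inb] <- mask$voxels[lin]
  if (any(mask$voxels > 0L) && !any(out > 0L)) {
    warn("transformed mask does not overlap the reference field of view; returning an empty mask")
  }
  label_mask(array(out, dim = d_ref), reference$affine)
}
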