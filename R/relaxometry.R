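#' Pair two echo images into a dual-echo acquisition
#'
#' A dual-echo fast (recovery) spin-echo acquisition samples the transverse
#' decay at two echo times, giving a proton-density-weighted image at the
#' early echo and a T2-weighted image at the late echo. Both images must
#' share the voxel grid and affine exactly.
#'
#' @param s1 `vol_img`: signal at the early echo `te1` (arbitrary units).
#' @param s2 `vol_img`: signal at the late echo `te2`, same grid.
#' @param te1,te2 Echo times in msec, `0 < te1 < te2`. Defaults 30/119 msec,
#'   a typical clinical dual-echo protocol at 3T.
#' @return An object of class `dual_echo`.
#' @export
dual_echo_acquisition <- function(s1, s2, te1 = 30, te2 = 119) {
  stopifnot(inherits(s1, "vol_img"), inherits(s2, "vol_img"))
  if (!identical(dim(s1$voxels), dim(s2$voxels)) ||
      max(abs(s1$affine - s2$affine)) > 1e-6) {
    ht2_abort("echo images must share grid dimensions and affine",
              "hippot2_error_grid_mismatch")
  }
  if (!(te1 > 0 && te2 > te1)) {
    ht2_abort("echo times must satisfy 0 < te1 < te2",
              "hippot2_error_bad_echo_times")
  }
  structure(list(s1 = s1, s2 = s2, te1 = te1, te2 = te2), class = "dual_echo")
}

#' Monoexponential forward signal model
#'
#' `S(TE) = A * exp(-TE / T2)`: the forward model behind both the T2 fit and
#' the digital phantom generator.
#'
#' @param a Amplitude (proton-density-weighted signal at TE = 0), `>= 0`.
#' @param t2 T2 relaxation time in msec, `> 0`.
#' @param te Echo time in msec, `>= 0`.
#' @return Predicted signal, vectorized over any argument.
#' @export
predict_signal <- function(a, t2, te) {
  if (any(t2 <= 0)) {
    ht2_abort("t2 must be positive", "hippot2_error_bad_t2")
  }
  stopifnot(all(a >= 0), all(te >= 0))
  a * exp(-te / t2)
}

#' Closed-form voxelwise T2 map from a dual-echo acquisition
#'
#' With only two echoes the monoexponential fit has the exact closed form
#' `T2 = (TE2 - TE1) / ln(S1 / S2)` per voxel. Voxels where the fit is
#' undefined or non-physical -- `S1 <= 0`, `S2 <= 0`, `S1 <= S2` (no decay),
#' or fitted T2 above `t2_max` -- are masked invalid rather than clamped;
#' their T2 is carried as `NA` and excluded from all downstream statistics.
#'
#' @param acq A [dual_echo_acquisition()].
#' @param t2_max Hard validity ceiling in msec (default 3000) keeping maps
#'   finite where the two echoes are nearly equal.
#' @return An object of class `t2_map`: fields `t2` (a `vol_img` in msec,
#'   `NA` where invalid) and `valid` (logical array, same grid).
#' @export
fit_t2_map <- function(acq, t2_max = 3000) {
  stopifnot(inherits(acq, "dual_echo"))
  s1 <- acq$s1$voxels
  s2 <- acq$s2$voxels
  dte <- acq$te2 - acq$te1
  t2 <- array(NA_real_, dim = dim(s1))
  ok <- is.finite(s1) & is.finite(s2) & s1 > 0 & s2 > 0 & s1 > s2
  t2[ok] <- dte / log(s1[ok] / s2[ok])
  ok <- ok & !is.na(t2) & t2 <= t2_max
  t2[!ok] <- NA_real_
  structure(
    list(t2 = volumetric_image(t2, acq$s1$affine), valid = ok),
    class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %s voxels, %.1f%% valid, median valid T2 %.1f msec\n",
              paste(dim(x$t2$voxels), collapse = " x "),
              100 * mean(x$valid),
              median(x$t2$voxels[x$valid])))
  invisible(x)
}

#' Write a T2 map (and its validity mask) as NIfTI
#'
#' The map is stored as float32 with msec noted in the header description;
#' invalid voxels are written as 0 and flagged 0 in the companion uint8
#' validity mask.
#'
#' @param t2map A `t2_map`.
#' @param path Output path for the map.
#' @param mask_path Optional output path for the validity mask.
#' @return `path`, invisibly.
#' @export
write_t2_map <- function(t2map, path, mask_path = NULL) {
  stopifnot(inherits(t2map, "t2_map"))
  vox <- t2map$t2$voxels
  vox[!t2map$valid] <- 0
  nii <- RNifti::asNifti(vox, datatype = "float")
  RNifti::sform(nii) <- structure(t2map$t2$affine, code = 2L)
  nii$descrip <- "T2 map [msec]"
  RNifti::writeNifti(nii, path)
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(array(as.integer(t2map$valid), dim = dim(vox)),
                         datatype = "uint8")
    RNifti::sform(m) <- structure(t2map$t2$affine, code = 2L)
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}
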