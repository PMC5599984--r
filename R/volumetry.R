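#' Fit the intracranial-volume correction model on healthy controls
#'
#' Ordinary least-squares regression of hippocampal volume on intracranial
#' volume (ICV) in controls. The stored slope and control ICV mean define
#' the residual ("covariance") head-size correction applied by
#' [correct_volume()], which keeps corrected volumes on their natural cm^3
#' scale.
#'
#' @param control_volumes Raw hippocampal volumes of controls, cm^3.
#' @param control_icvs Matching intracranial volumes, cm^3.
#' @return An object of class `icv_model`: `slope_b` (cm^3 per cm^3 ICV),
#'   `icv_mean_controls`, `n_controls`, plus the underlying `lm` fit.
#' @export
fit_icv_model <- function(control_volumes, control_icvs) {
  stopifnot(length(control_volumes) == length(control_icvs))
  if (length(control_volumes) < 3L) {
    ht2_abort("ICV model needs at least 3 controls", "hippot2_error_icv_model")
  }
  if (var(control_icvs) <= 0) {
    ht2_abort("ICV variance is zero: slope is undefined", "hippot2_error_icv_model")
  }
  fit <- lm(control_volumes ~ control_icvs)
  structure(list(
    slope_b = unname(coef(fit)[2]),
    icv_mean_controls = mean(control_icvs),
    n_controls = length(control_volumes),
    fit = fit),
    class = "icv_model")
}

#' Correct a hippocampal volume for head size
#'
#' `corrected = raw - slope_b * (icv - mean ICV of controls)`. By OLS
#' residual orthogonality, corrected control volumes are uncorrelated with
#' ICV and their group mean is preserved exactly.
#'
#' @param raw_volume Raw volume(s), cm^3.
#' @param icv Intracranial volume(s), cm^3.
#' @param model An [fit_icv_model()] object.
#' @return Corrected volume(s), cm^3.
#' @export
correct_volume <- function(raw_volume, icv, model) {
  stopifnot(inherits(model, "icv_model"))
  raw_volume - model$slope_b * (icv - model$icv_mean_controls)
}

#' @export
print.icv_model <- function(x, ...) {
  cat(sprintf("<icv_model> slope %.4g cm^3/cm^3, control ICV mean %.1f cm^3 (n = %d)\n",
              x$slope_b, x$icv_mean_controls, x$n_controls))
  invisible(x)
}

#' @export
tidy.icv_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "icv"),
         estimate = s[, 1],
         std_error = s[, 2],
         statistic = s[, 3],
         p_value = s[, 4])
}

#' @export
glance.icv_model <- function(x, ...) {
  tibble(slope_b = x$slope_b,
         icv_mean_controls = x$icv_mean_controls,
         n_controls = x$n_controls,
         r_squared = summary(x$fit)$r.squared)
}

#' Raw structure volume from a label mask
#'
#' Voxel count times voxel volume, in cm^3, per label.
#'
#' @param mask A `label_mask` on its native grid.
#' @return Tibble with `label`, `n_voxels`, `volume_cm3`.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  labs <- setdiff(sort(unique(as.vector(mask$voxels))), 0L)
  vv <- voxel_volume_mm3(mask)
  tibble(
    label = labs,
    n_voxels = vapply(labs, function(l) sum(mask$voxels == l), integer(1)),
    volume_cm3 = vapply(labs, function(l) sum(mask$voxels == l), integer(1)) * vv / 1000)
}
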