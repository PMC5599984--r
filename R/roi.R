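#' ROI post-processing policy
#'
#' Controls how a hippocampal segmentation is turned into a CSF-free region
#' of interest on the T2 map: morphological erosion at the boundary (to
#' reduce partial-volume voxels) followed by removal of voxels whose T2
#' exceeds a CSF cutoff.
#'
#' @param erosion_iterations Number of erosion passes (default 1).
#' @param erosion_mode `"in-plane-2D"` (default): 3x3 square structuring
#'   element applied within each slice, leaving the through-plane direction
#'   untouched -- appropriate for thick-slice (e.g. 4 mm) coronal
#'   acquisitions where 3-D erosion would destroy through-plane structure.
#'   `"full-3D"`: 3x3x3 6-connected (face-adjacent) element.
#' @param csf_threshold CSF exclusion cutoff in msec (default 170). Voxels
#'   with T2 strictly greater than the cutoff are removed; a voxel at
#'   exactly the cutoff is retained.
#' @param min_voxels Minimum retained voxels for a measurement to be
#'   considered reliable (default 20).
#' @param slice_axis Array axis holding the through-plane (slice) direction
#'   (default 3).
#' @return An object of class `roi_policy`.
#' @export
roi_policy <- function(erosion_iterations = 1L,
                       erosion_mode = c("in-plane-2D", "full-3D"),
                       csf_threshold = 170,
                       min_voxels = 20L,
                       slice_axis = 3L) {
  erosion_mode <- match.arg(erosion_mode)
  stopifnot(erosion_iterations >= 0, csf_threshold > 0, min_voxels >= 1,
            slice_axis %in% 1:3)
  structure(list(erosion_iterations = as.integer(erosion_iterations),
                 erosion_mode = erosion_mode,
                 csf_threshold = csf_threshold,
                 min_voxels = as.integer(min_voxels),
                 slice_axis = as.integer(slice_axis)),
            class = "roi_policy")
}

# result[v] = b[v + off], FALSE outside the grid
shift_logical <- function(b, off) {
  d <- dim(b)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      dst[[a]] <- seq_len(d[a] - o)
      src[[a]] <- seq_len(d[a] - o) + o
    } else {
      if (-o >= d[a]) return(out)
      dst[[a]] <- seq_len(d[a] + o) - o
      src[[a]] <- seq_len(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- b[src[[1]], src[[2]], src[[3]]]
  out
}

erosion_offsets <- function(mode, slice_axis) {
  if (mode == "in-plane-2D") {
    inplane <- setdiff(1:3, slice_axis)
    offs <- expand.grid(a = -1:1, b = -1:1)
    lapply(seq_len(nrow(offs)), function(r) {
      o <- c(0L, 0L, 0L)
      o[inplane] <- c(offs$a[r], offs$b[r])
      o
    })
  } else {
    list(c(0L, 0L, 0L),
         c(1L, 0L, 0L), c(-1L, 0L, 0L),
         c(0L, 1L, 0L), c(0L, -1L, 0L),
         c(0L, 0L, 1L), c(0L, 0L, -1L))
  }
}

#' Morphological erosion of a label mask
#'
#' Each label is eroded independently: a voxel keeps its label only if the
#' whole structuring element around it carries that label (outside the grid
#' counts as background). The output is always a subset of the input, so
#' erosion can never move the ROI into neighbouring tissue.
#'
#' @param mask A `label_mask`.
#' @param policy An [roi_policy()] supplying the element, mode and
#'   iteration count.
#' @return The eroded `label_mask` (possibly empty).
#' @export
erode_mask <- function(mask, policy = roi_policy()) {
  stopifnot(inherits(mask, "label_mask"), inherits(policy, "roi_policy"))
  if (policy$erosion_iterations == 0L) return(mask)
  offs <- erosion_offsets(policy$erosion_mode, policy$slice_axis)
  out <- array(0L, dim = dim(mask$voxels))
  for (lab in setdiff(sort(unique(as.vector(mask$voxels))), 0L)) {
    b <- mask$voxels == lab
    for (it in seq_len(policy$erosion_iterations)) {
      b <- Reduce(`&`, lapply(offs, function(o) shift_logical(b, o)))
    }
    out[b] <- lab
  }
  label_mask(out, mask$affine)
}

#' Morphological dilation of a label mask
#'
#' The dual of [erode_mask()] under the same structuring element: a
#' background voxel takes a label if any element neighbour carries it.
#' Used by the phantom tools to emulate segmentations that overreach into
#' the partial-volume shell at the structure boundary. Labels are dilated
#' in ascending order; disjointness is preserved for well-separated
#' structures (existing labels are never overwritten).
#'
#' @inheritParams erode_mask
#' @return The dilated `label_mask`.
#' @export
dilate_mask <- function(mask, policy = roi_policy()) {
  stopifnot(inherits(mask, "label_mask"), inherits(policy, "roi_policy"))
  if (policy$erosion_iterations == 0L) return(mask)
  offs <- erosion_offsets(policy$erosion_mode, policy$slice_axis)
  out <- mask$voxels
  for (lab in setdiff(sort(unique(as.vector(mask$voxels))), 0L)) {
    b <- mask$voxels == lab
    for (it in seq_len(policy$erosion_iterations)) {
      b <- Reduce(`|`, lapply(offs, function(o) shift_logical(b, o)))
    }
    out[b & out == 0L] <- lab
  }
  label_mask(out, mask$affine)
}

#' Remove CSF-contaminated and invalid voxels from an ROI
#'
#' Voxels whose fitted T2 is strictly greater than the policy's
#' `csf_threshold` (default 170 msec), or whose fit is invalid, are removed
#' from the mask. This is the partial-volume guard that keeps
#' cerebrospinal fluid (T2 of order seconds) out of the hippocampal mean.
#' Per-label exclusion counts are attached as attributes
#' `n_excluded_csf` / `n_invalid` and picked up by [summarize_roi()].
#'
#' @param mask A `label_mask` on the T2-map grid (typically already eroded).
#' @param t2map A `t2_map` on the same grid.
#' @param policy An [roi_policy()].
#' @return The filtered `label_mask`.
#' @export
exclude_csf <- function(mask, t2map, policy = roi_policy()) {
  stopifnot(inherits(mask, "label_mask"), inherits(t2map, "t2_map"))
  check_same_grid(mask, t2map$t2)
  labs <- setdiff(sort(unique(as.vector(mask$voxels))), 0L)
  t2 <- t2map$t2$voxels
  keep <- t2map$valid & !is.na(t2) & t2 <= policy$csf_threshold
  out_vox <- mask$voxels
  out_vox[!keep] <- 0L
  n_csf <- n_inv <- setNames(integer(length(labs)), as.character(labs))
  for (lab in labs) {
    inlab <- mask$voxels == lab
    n_inv[as.character(lab)] <- sum(inlab & !t2map$valid)
    n_csf[as.character(lab)] <- sum(inlab & t2map$valid & t2 > policy$csf_threshold,
                                    na.rm = TRUE)
  }
  out <- label_mask(out_vox, mask$affine)
  attr(out, "n_excluded_csf") <- n_csf
  attr(out, "n_invalid") <- n_inv
  out
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      max(abs(a$affine - b$affine)) > 1e-4) {
    ht2_abort("images must share grid dimensions and affine",
              "hippot2_error_grid_mismatch")
  }
  invisible(TRUE)
}

#' Summarize an ROI on a T2 map
#'
#' Computes the voxel-pooled arithmetic mean and SD (n-1 denominator) of T2
#' over all retained valid voxels of each label -- pooled across slices,
#' not slice-averaged. Measurements with fewer than `policy$min_voxels`
#' retained voxels are flagged unreliable.
#'
#' @param mask A `label_mask`, already eroded and CSF-excluded (see
#'   [measure_hippocampal_t2()] for the full chain).
#' @param t2map A `t2_map` on the same grid.
#' @param policy An [roi_policy()].
#' @return A tibble with one row per label: `label`, `structure`,
#'   `mean_t2_ms`, `sd_t2_ms`, `n_voxels`, `n_excluded_csf`, `n_invalid`,
#'   `reliable`.
#' @export
summarize_roi <- function(mask, t2map, policy = roi_policy()) {
  stopifnot(inherits(mask, "label_mask"), inherits(t2map, "t2_map"))
  check_same_grid(mask, t2map$t2)
  labs <- setdiff(sort(unique(as.vector(mask$voxels))), 0L)
  if (length(labs) == 0L) {
    ht2_abort("ROI is empty: no labeled voxels remain", "hippot2_error_empty_roi")
  }
  n_csf_attr <- attr(mask, "n_excluded_csf") %||% integer()
  n_inv_attr <- attr(mask, "n_invalid") %||% integer()
  lab_names <- names(hippocampus_labels())[match(labs, hippocampus_labels())]
  lab_names[is.na(lab_names)] <- paste0("label_", labs[is.na(lab_names)])
  rows <- lapply(seq_along(labs), function(i) {
    lab <- labs[i]
    vals <- t2map$t2$voxels[mask$voxels == lab & t2map$valid]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      ht2_abort(sprintf("ROI for label %d (%s) is empty after filtering",
                        lab, lab_names[i]),
                "hippot2_error_empty_roi")
    }
    tibble(
      label = lab,
      structure = lab_names[i],
      mean_t2_ms = mean(vals),
      sd_t2_ms = if (length(vals) > 1L) sd(vals) else NA_real_,
      n_voxels = length(vals),
      n_excluded_csf = as.integer(n_csf_attr[as.character(lab)] %|0|% 0L),
      n_invalid = as.integer(n_inv_attr[as.character(lab)] %|0|% 0L),
      reliable = length(vals) >= policy$min_voxels)
  })
  dplyr::bind_rows(rows)
}

# default for missing / NA named-vector lookups
`%|0|%` <- function(x, default) {
  if (length(x) == 0L || is.na(x)) default else x
}

#' Full ROI measurement chain: erode, CSF-exclude, summarize
#'
#' Applies the post-processing order resample (upstream), erode, CSF
#' exclusion, then voxel-pooled summary.
#'
#' @inheritParams summarize_roi
#' @param mask A `label_mask` on the T2-map grid (already resampled).
#' @return The [summarize_roi()] tibble.
#' @export
measure_hippocampal_t2 <- function(mask, t2map, policy = roi_policy()) {
  eroded <- erode_mask(mask, policy)
  cleaned <- exclude_csf(eroded, t2map, policy)
  summarize_roi(cleaned, t2map, policy)
}

#' Anteroposterior slice profile of ROI T2
#'
#' Per-slice mean T2 along the through-plane (coronal slice) axis, ordered
#' anterior to posterior. The anterior direction is read off the affine:
#' the world y (posterior-to-anterior in RAS+) component of the slice-axis
#' column determines the ordering. Only slices with at least one retained
#' voxel are reported.
#'
#' @inheritParams summarize_roi
#' @param label Structure label to profile (default 1, left hippocampus).
#' @return A tibble of class `t2_slice_profile`: `slice_index` (0-based
#'   grid slice), `y_mm` (world y of the slice center), `mean_t2_ms`,
#'   `sd_t2_ms`, `n_voxels`, ordered anterior to posterior.
#' @export
slice_profile <- function(mask, t2map, policy = roi_policy(), label = 1L) {
  stopifnot(inherits(mask, "label_mask"), inherits(t2map, "t2_map"))
  check_same_grid(mask, t2map$t2)
  ax <- policy$slice_axis
  sel <- mask$voxels == label & t2map$valid & !is.na(t2map$t2$voxels)
  if (!any(sel)) {
    ht2_abort(sprintf("ROI for label %d is empty", label), "hippot2_error_empty_roi")
  }
  slice_of <- slice.index(sel, ax)[sel]
  vals <- t2map$t2$voxels[sel]
  per <- dplyr::summarise(
    dplyr::group_by(tibble(slice = slice_of, t2 = vals), .data$slice),
    mean_t2_ms = mean(.data$t2),
    sd_t2_ms = if (dplyr::n() > 1L) sd(.data$t2) else NA_real_,
    n_voxels = dplyr::n(),
    .groups = "drop")
  aff <- mask$affine
  per$slice_index <- per$slice - 1L
  per$y_mm <- aff[2, ax] * per$slice_index + aff[2, 4]
  # RAS+: +y is anterior, so anterior-first means descending y; with a
  # y-degenerate affine (profile axis not AP) fall back to ascending index
  if (abs(aff[2, ax]) > 1e-9) {
    per <- per[order(-per$y_mm), ]
  } else {
    per <- per[order(per$slice_index), ]
  }
  out <- per[, c("slice_index", "y_mm", "mean_t2_ms", "sd_t2_ms", "n_voxels")]
  class(out) <- c("t2_slice_profile", class(out))
  out
}
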