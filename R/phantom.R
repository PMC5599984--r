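#' Specification of the digital dual-echo phantom
#'
#' Defines a brain-like phantom on a coronal dual-echo grid: a gray-matter
#' shell around a white-matter core, two hippocampal ellipsoids, and CSF
#' ventricle compartments abutting each hippocampus medially (so that CSF
#' partial-volume contamination of an unprocessed hippocampal ROI is part
#' of the simulated conditions). Grid axes are (left-right, inferior-
#' superior, slice); the slice axis is anterior-posterior, matching a
#' coronal acquisition, and the default grid is a 4x in-plane downscale of
#' a 512x512 clinical matrix at 4 mm slice thickness.
#'
#' @param dim Grid dimensions (default `c(128, 128, 32)`).
#' @param voxel_mm Voxel size in mm (default `c(0.43, 0.43, 4)`:
#'   in-plane x, in-plane z, 4 mm coronal slices).
#' @param t2_ms Named true T2 per compartment, msec. Defaults: WM 80,
#'   GM 110, hippocampi 115, CSF 2000.
#' @param pd Named proton-density amplitude per compartment (arbitrary
#'   units). Background (air) has zero signal.
#' @param te1,te2 Echo times in msec (default 30/119).
#' @param noise_sigma Rician noise sigma per channel. `NULL` (default)
#'   derives sigma from `snr` as (hippocampal late-echo signal) / snr.
#' @param snr Late-echo hippocampal signal-to-noise ratio used when
#'   `noise_sigma` is `NULL` (default 50). Set `noise_sigma = 0` for a
#'   noiseless phantom.
#' @param hippo_scale Scale factor on the hippocampal semi-axes (default 1
#'   gives ~3 cm^3 per hippocampus on the default grid, healthy-control
#'   anatomy; ~0.87 gives the ~2 cm^3 of a sclerotic hippocampus).
#' @param shift_vox Integer voxel translation applied to every compartment
#'   center (repositioning between simulated scans).
#' @param seed Optional integer seed; generation is a pure function of it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(128L, 128L, 32L),
                         voxel_mm = c(0.43, 0.43, 4),
                         t2_ms = c(hippo_left = 115, hippo_right = 115,
                                   gm = 110, wm = 80, csf = 2000),
                         pd = c(hippo_left = 90, hippo_right = 90,
                                gm = 85, wm = 70, csf = 100),
                         te1 = 30, te2 = 119,
                         noise_sigma = NULL, snr = 50,
                         hippo_scale = 1,
                         shift_vox = c(0L, 0L, 0L),
                         seed = NULL) {
  comps <- c("hippo_left", "hippo_right", "gm", "wm", "csf")
  stopifnot(length(dim) == 3L, all(dim >= 16L),
            length(voxel_mm) == 3L, all(voxel_mm > 0),
            all(comps %in% names(t2_ms)), all(comps %in% names(pd)),
            all(t2_ms > 0), all(pd >= 0), te1 > 0, te2 > te1)
  if (is.null(noise_sigma)) {
    noise_sigma <- unname(pd["hippo_left"] * exp(-te2 / t2_ms["hippo_left"]) / snr)
  }
  stopifnot(noise_sigma >= 0)
  stopifnot(hippo_scale > 0)
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 t2_ms = t2_ms[comps], pd = pd[comps],
                 te1 = te1, te2 = te2, noise_sigma = noise_sigma,
                 hippo_scale = hippo_scale,
                 shift_vox = as.integer(round(shift_vox)), seed = seed),
            class = "phantom_spec")
}

# coronal affine: axis1 -> world x, axis2 -> world z, axis3 (slices) -> world y
phantom_affine <- function(dim, voxel_mm) {
  aff <- matrix(0, 4, 4)
  aff[1, 1] <- voxel_mm[1]
  aff[3, 2] <- voxel_mm[2]
  aff[2, 3] <- voxel_mm[3]
  aff[4, 4] <- 1
  aff[1:3, 4] <- -c(voxel_mm[1] * (dim[1] - 1), voxel_mm[3] * (dim[3] - 1),
                    voxel_mm[2] * (dim[2] - 1)) / 2
  aff
}

ellipsoid_mask <- function(dim, center, semi) {
  u1 <- (((seq_len(dim[1]) - 1) - center[1]) / semi[1])^2
  u2 <- (((seq_len(dim[2]) - 1) - center[2]) / semi[2])^2
  u3 <- (((seq_len(dim[3]) - 1) - center[3]) / semi[3])^2
  outer(outer(u1, u2, `+`), u3, `+`) <= 1
}

phantom_geometry <- function(spec) {
  d <- spec$dim
  c0 <- (d - 1) / 2 + spec$shift_vox
  list(
    brain = list(center = c0, semi = c(0.45, 0.45, 0.47) * d),
    wm = list(center = c0, semi = c(0.36, 0.36, 0.38) * d),
    hippo_left = list(center = c0 + c(-0.19, -0.06, 0) * d,
                      semi = c(0.096, 0.078, 0.246) * d * spec$hippo_scale),
    hippo_right = list(center = c0 + c(0.19, -0.06, 0) * d,
                       semi = c(0.096, 0.078, 0.246) * d * spec$hippo_scale),
    csf_left = list(center = c0 + c(-0.08, 0.02, 0) * d,
                    semi = c(0.07, 0.08, 0.25) * d),
    csf_right = list(center = c0 + c(0.08, 0.02, 0) * d,
                     semi = c(0.07, 0.08, 0.25) * d))
}

#' Generate a dual-echo digital phantom with ground truth
#'
#' Builds the compartment label map, the true T2 map, and the two echo
#' images `S(TE) = PD * exp(-TE / T2)` with Rician noise (the magnitude-MRI
#' noise model: `sqrt((S + sigma * Z1)^2 + (sigma * Z2)^2)`). Generation is
#' deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `t2_phantom`: `labels` (ground-truth
#'   `label_mask` over all compartments, see [hippocampus_labels()] and
#'   [tissue_labels()]), `t2_truth` (`vol_img`, msec; 0 outside the head),
#'   `acq` (a [dual_echo_acquisition()]), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  run <- function() {
    d <- spec$dim
    geo <- phantom_geometry(spec)
    labels <- array(0L, dim = d)
    labels[ellipsoid_mask(d, geo$brain$center, geo$brain$semi)] <- tissue_labels()["gm"]
    labels[ellipsoid_mask(d, geo$wm$center, geo$wm$semi)] <- tissue_labels()["wm"]
    labels[ellipsoid_mask(d, geo$csf_left$center, geo$csf_left$semi)] <- tissue_labels()["csf"]
    labels[ellipsoid_mask(d, geo$csf_right$center, geo$csf_right$semi)] <- tissue_labels()["csf"]
    labels[ellipsoid_mask(d, geo$hippo_left$center, geo$hippo_left$semi)] <-
      hippocampus_labels()["left"]
    labels[ellipsoid_mask(d, geo$hippo_right$center, geo$hippo_right$semi)] <-
      hippocampus_labels()["right"]
    check_phantom_invariants(labels)

    lab2comp <- c("1" = "hippo_left", "2" = "hippo_right", "3" = "gm",
                  "4" = "wm", "5" = "csf")
    t2 <- array(0, dim = d)
    pd <- array(0, dim = d)
    for (lab in names(lab2comp)) {
      sel <- labels == as.integer(lab)
      t2[sel] <- spec$t2_ms[[lab2comp[[lab]]]]
      pd[sel] <- spec$pd[[lab2comp[[lab]]]]
    }
    s1 <- pd
    s2 <- pd
    inside <- t2 > 0
    s1[inside] <- predict_signal(pd[inside], t2[inside], spec$te1)
    s2[inside] <- predict_signal(pd[inside], t2[inside], spec$te2)
    if (spec$noise_sigma > 0) {
      s1 <- rician(s1, spec$noise_sigma)
      s2 <- rician(s2, spec$noise_sigma)
    }
    aff <- phantom_affine(d, spec$voxel_mm)
    list(labels = label_mask(labels, aff),
         t2_truth = volumetric_image(t2, aff),
         acq = dual_echo_acquisition(volumetric_image(s1, aff),
                                     volumetric_image(s2, aff),
                                     te1 = spec$te1, te2 = spec$te2),
         spec = spec)
  }
  out <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  class(out) <- "t2_phantom"
  out
}

rician <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
}

check_phantom_invariants <- function(labels) {
  hl <- hippocampus_labels()
  csf <- tissue_labels()["csf"]
  for (side in names(hl)) {
    b <- labels == hl[[side]]
    if (sum(b) < 500L) {
      ht2_abort(sprintf("%s hippocampus has %d voxels (< 500): geometry too small",
                        side, sum(b)), "hippot2_error_phantom_geometry")
    }
    near_csf <- FALSE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      near_csf <- near_csf || any(shift_logical(labels == csf, o) & b)
      if (near_csf) break
    }
    if (!near_csf) {
      ht2_abort(sprintf("no CSF voxel is 6-adjacent to the %s hippocampus", side),
                "hippot2_error_phantom_geometry")
    }
  }
  invisible(TRUE)
}

#' Extract the hippocampal segmentation from phantom truth labels
#'
#' @param labels The phantom's ground-truth `label_mask`.
#' @param dilate Number of one-voxel in-plane dilations applied to the
#'   truth hippocampi (default 0). `dilate = 1` emulates a realistic
#'   automated segmentation that overreaches into the partial-volume
#'   shell at the boundary, picking up the abutting CSF -- the failure
#'   mode the erode-and-threshold post-processing is designed to undo.
#' @return A `label_mask` retaining only labels 1 (left) and 2 (right),
#'   as an automated segmentation tool would supply.
#' @export
hippocampus_mask <- function(labels, dilate = 0L) {
  vox <- labels$voxels
  vox[!(vox %in% hippocampus_labels())] <- 0L
  out <- label_mask(vox, labels$affine)
  if (dilate > 0L) {
    out <- dilate_mask(out, roi_policy(erosion_iterations = dilate))
  }
  out
}

#' Simulate manual elliptical-ROI T2 measurement
#'
#' Emulates the conventional manual protocol: on each coronal slice where
#' the structure appears, an elliptical ROI of about `roi_area_mm2`
#' (aspect 2:1, major axis along the first in-plane direction) is placed
#' at the structure's in-plane centroid plus Gaussian placement jitter,
#' and the overall manual T2 is the mean over all ellipse voxels across
#' slices. No erosion and no CSF threshold are applied -- jittered
#' placements can therefore pick up CSF partial volume, which is exactly
#' the failure mode whole-ROI automated measurement avoids.
#'
#' @param mask A `label_mask` holding the structure (unprocessed
#'   segmentation).
#' @param t2map A `t2_map` on the same grid.
#' @param label Structure label (default 1).
#' @param roi_area_mm2 Target ellipse area per slice (default 20 mm^2).
#' @param jitter_mm SD of the Gaussian in-plane placement jitter
#'   (default 1 mm; 0 for perfectly centered placement).
#' @param slice_axis Through-plane axis (default 3).
#' @param seed Optional seed for the jitter.
#' @return A list: `mean_t2_ms` (overall manual value) and `per_slice`
#'   tibble (`slice_index`, `mean_t2_ms`, `n_voxels`).
#' @export
simulate_manual_rois <- function(mask, t2map, label = 1L, roi_area_mm2 = 20,
                                 jitter_mm = 1, slice_axis = 3L, seed = NULL) {
  stopifnot(inherits(mask, "label_mask"), inherits(t2map, "t2_map"))
  check_same_grid(mask, t2map$t2)
  run <- function() {
    d <- dim(mask$voxels)
    inplane <- setdiff(1:3, slice_axis)
    vs <- voxel_size(mask)
    b_mm <- sqrt(roi_area_mm2 / (2 * pi))  # semi-minor; semi-major = 2 * b
    semi_vox <- c(2 * b_mm / vs[inplane[1]], b_mm / vs[inplane[2]])
    sel <- mask$voxels == label
    if (!any(sel)) {
      ht2_abort(sprintf("structure label %d absent from mask", label),
                "hippot2_error_empty_roi")
    }
    idx <- which(sel, arr.ind = TRUE)
    slices <- sort(unique(idx[, slice_axis]))
    per <- purrr::map_dfr(slices, function(s) {
      in_slice <- idx[idx[, slice_axis] == s, , drop = FALSE]
      ctr <- colMeans(in_slice)[inplane] +
        rnorm(2) * jitter_mm / vs[inplane]
      u <- as.matrix(expand.grid(a = seq_len(d[inplane[1]]),
                                 b = seq_len(d[inplane[2]])))
      inside <- ((u[, 1] - ctr[1]) / semi_vox[1])^2 +
        ((u[, 2] - ctr[2]) / semi_vox[2])^2 <= 1
      coords <- matrix(0L, nrow = sum(inside), ncol = 3)
      coords[, inplane[1]] <- u[inside, 1]
      coords[, inplane[2]] <- u[inside, 2]
      coords[, slice_axis] <- s
      keep <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
        coords[, 2] >= 1 & coords[, 2] <= d[2]
      coords <- coords[keep, , drop = FALSE]
      vals <- t2map$t2$voxels[coords]
      ok <- t2map$valid[coords] & !is.na(vals)
      tibble(slice_index = s - 1L,
             mean_t2_ms = if (any(ok)) mean(vals[ok]) else NA_real_,
             n_voxels = sum(ok))
    })
    per <- per[per$n_voxels > 0L, ]
    list(mean_t2_ms = sum(per$mean_t2_ms * per$n_voxels) / sum(per$n_voxels),
         per_slice = per)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulated scan-rescan reproducibility study
#'
#' For each simulated subject, two scans of the same phantom anatomy are
#' generated with independent Rician noise and independent whole-head
#' repositioning of up to `reposition_vox` voxels per axis. Each scan is
#' measured two ways per hippocampus: the automated whole-ROI pipeline
#' (erode, CSF-exclude, voxel-pooled mean) and simulated manual elliptical
#' ROIs with placement jitter. The spread of scan-rescan differences
#' compares the reproducibility of the two methods.
#'
#' @param n_subjects Number of simulated subjects (two hippocampi each).
#' @param spec Base [phantom_spec()] (noise level and geometry).
#' @param policy [roi_policy()] for the automated measurement.
#' @param reposition_vox Maximum integer repositioning per axis between
#'   scans (default 1).
#' @param manual_roi_area_mm2,manual_jitter_mm Manual-ROI simulation
#'   parameters (defaults 20 mm^2, 1 mm).
#' @param seed Seed making the whole study reproducible.
#' @return A tibble: `subject`, `side`, `scan` (1/2), `automated`,
#'   `manual` (mean T2, msec).
#' @export
simulate_rescan_study <- function(n_subjects = 100, spec = phantom_spec(),
                                  policy = roi_policy(), reposition_vox = 1L,
                                  manual_roi_area_mm2 = 20, manual_jitter_mm = 1,
                                  seed = 1L) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(subj) {
      purrr::map_dfr(1:2, function(scan) {
        shift <- sample(seq(-reposition_vox, reposition_vox), 3, replace = TRUE)
        sp <- spec
        sp$shift_vox <- as.integer(shift)
        sp$seed <- NULL
        ph <- generate_phantom(sp)
        t2map <- fit_t2_map(ph$acq)
        seg <- hippocampus_mask(ph$labels)
        auto <- measure_hippocampal_t2(seg, t2map, policy)
        purrr::map_dfr(names(hippocampus_labels()), function(side) {
          lab <- hippocampus_labels()[[side]]
          man <- simulate_manual_rois(seg, t2map, label = lab,
                                      roi_area_mm2 = manual_roi_area_mm2,
                                      jitter_mm = manual_jitter_mm)
          tibble(subject = subj, side = side, scan = scan,
                 automated = auto$mean_t2_ms[auto$label == lab],
                 manual = man$mean_t2_ms)
        })
      })
    })
  })
}

#' Scan-rescan difference SD per measurement method
#'
#' @param study Output of [simulate_rescan_study()].
#' @return Tibble: `method`, `mean_diff`, `sd_diff`, `n_pairs`.
#' @export
rescan_sd <- function(study) {
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(study, c("automated", "manual"),
                        names_to = "method", values_to = "t2"),
    names_from = "scan", values_from = "t2", names_prefix = "scan_")
  dplyr::summarise(
    dplyr::group_by(wide, .data$method),
    mean_diff = mean(.data$scan_1 - .data$scan_2),
    sd_diff = sd(.data$scan_1 - .data$scan_2),
    n_pairs = dplyr::n(),
    .groups = "drop")
}
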