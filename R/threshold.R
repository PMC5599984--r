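#' Conventional tissue-class label table
#'
#' Labels used by the phantom generator and the calibration tools for
#' tissue-class maps: gray matter, white matter and CSF (hippocampal labels
#' 1/2 come first, see [hippocampus_labels()]).
#'
#' @return Named integer vector.
#' @export
tissue_labels <- function() c(gm = 3L, wm = 4L, csf = 5L)

#' Collect per-tissue T2 samples from a labeled T2 map
#'
#' Gathers the valid-voxel T2 values of each tissue class (gray matter,
#' white matter, CSF) from a tissue-class label map aligned to a T2 map.
#' These distributions drive the empirical determination of the CSF
#' exclusion cutoff in [calibrate_cutoff()]. When tissue probability maps
#' are the source, hard labels should be taken at high probability
#' (p > 0.9) upstream to limit partial-volume samples.
#'
#' @param tissue_mask A `label_mask` of tissue classes on the T2-map grid.
#' @param t2map A `t2_map` on the same grid.
#' @param labels Named integer vector mapping class names to labels
#'   (default [tissue_labels()]); must include `gm` and `csf`.
#' @return A tibble with columns `tissue` and `t2_ms`, one row per valid
#'   voxel sample.
#' @export
collect_tissue_t2 <- function(tissue_mask, t2map, labels = tissue_labels()) {
  stopifnot(inherits(tissue_mask, "label_mask"), inherits(t2map, "t2_map"))
  check_same_grid(tissue_mask, t2map$t2)
  stopifnot(all(c("gm", "csf") %in% names(labels)))
  out <- purrr::map_dfr(names(labels), function(cls) {
    sel <- tissue_mask$voxels == labels[[cls]] & t2map$valid
    vals <- t2map$t2$voxels[sel]
    vals <- vals[!is.na(vals)]
    tibble(tissue = cls, t2_ms = vals)
  })
  counts <- table(factor(out$tissue, levels = names(labels)))
  empty <- names(counts)[counts == 0L]
  if (length(empty) > 0L) {
    ht2_abort(sprintf("no valid T2 samples for tissue class(es): %s",
                      paste(empty, collapse = ", ")),
              "hippot2_error_missing_tissue")
  }
  out
}

#' Empirically calibrate the CSF-exclusion T2 cutoff
#'
#' Operationalizes the visual "optimal cutoff between the upper tail of
#' gray matter and the lower tail of CSF" as the equal-weight
#' misclassification minimizer: a grid search at 1 msec resolution over
#' `[median(GM), median(CSF)]` minimizing `P(GM > c) + P(CSF <= c)`, i.e.
#' the GM fraction a downstream `exclude_csf()` at cutoff `c` would remove
#' plus the CSF fraction it would retain. Ties are broken toward the lower
#' candidate. The shipped pipeline default stays at 170 msec; calibration
#' is a recalibration path for other scanners or sequences.
#'
#' @param samples A tibble as returned by [collect_tissue_t2()] (columns
#'   `tissue`, `t2_ms`), or a list with numeric elements `gm` and `csf`.
#' @param resolution_ms Grid step in msec (default 1).
#' @return An object of class `t2_threshold`: list with `cutoff_ms`,
#'   `gm_tail_fraction` (GM above cutoff), `csf_tail_fraction` (CSF at or
#'   below cutoff), `loss`, and per-class sample sizes.
#' @export
calibrate_cutoff <- function(samples, resolution_ms = 1) {
  if (is.data.frame(samples)) {
    gm <- samples$t2_ms[samples$tissue == "gm"]
    csf <- samples$t2_ms[samples$tissue == "csf"]
  } else {
    gm <- samples$gm
    csf <- samples$csf
  }
  gm <- gm[is.finite(gm)]
  csf <- csf[is.finite(csf)]
  if (length(gm) < 100L || length(csf) < 100L) {
    ht2_abort("calibration needs at least 100 valid samples per class",
              "hippot2_error_calibration")
  }
  m_gm <- median(gm)
  m_csf <- median(csf)
  if (m_gm >= m_csf) {
    ht2_abort("GM and CSF T2 distributions are not separable (GM median >= CSF median)",
              "hippot2_error_calibration")
  }
  grid <- seq(ceiling(m_gm), floor(m_csf), by = resolution_ms)
  if (length(grid) == 0L) grid <- (m_gm + m_csf) / 2
  loss <- vapply(grid, function(cc) mean(gm > cc) + mean(csf <= cc), numeric(1))
  best <- which.min(loss) # which.min returns the first (lowest) minimizer
  structure(list(
    cutoff_ms = grid[best],
    gm_tail_fraction = mean(gm > grid[best]),
    csf_tail_fraction = mean(csf <= grid[best]),
    loss = loss[best],
    n_gm = length(gm),
    n_csf = length(csf)),
    class = "t2_threshold")
}

#' @export
print.t2_threshold <- function(x, ...) {
  cat(sprintf(
    "<t2_threshold> cutoff %.0f msec (GM tail %.3g, CSF tail %.3g; n = %d GM / %d CSF)\n",
    x$cutoff_ms, x$gm_tail_fraction, x$csf_tail_fraction, x$n_gm, x$n_csf))
  invisible(x)
}

#' @export
glance.t2_threshold <- function(x, ...) {
  tibble(cutoff_ms = x$cutoff_ms,
         gm_tail_fraction = x$gm_tail_fraction,
         csf_tail_fraction = x$csf_tail_fraction,
         loss = x$loss,
         n_gm = x$n_gm,
         n_csf = x$n_csf)
}
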