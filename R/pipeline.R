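#' Normative reference ranges from group parameters
#'
#' Derives the shipped normative ranges from the control-group parameters:
#' pooled bilateral ranges for corrected volume and T2 (a single interval
#' over both sides) plus the per-side T2 ranges.
#'
#' @param params Group parameter tibble ([default_group_params()] layout).
#' @return A tibble: `measure`, `side`, `center`, `sd`, `lower`, `upper`.
#' @export
normative_reference <- function(params = default_group_params()) {
  ctrl <- params[params$group == "control", ]
  stopifnot(nrow(ctrl) == 2L)
  ctrl <- ctrl[match(c("left", "right"), ctrl$side), ]
  gs <- function(m, s, n) group_stats(m, s, n)
  t2_l <- gs(ctrl$t2_mean[1], ctrl$t2_sd[1], ctrl$n[1])
  t2_r <- gs(ctrl$t2_mean[2], ctrl$t2_sd[2], ctrl$n[2])
  vol_l <- gs(ctrl$vol_mean[1], ctrl$vol_sd[1], ctrl$n[1])
  vol_r <- gs(ctrl$vol_mean[2], ctrl$vol_sd[2], ctrl$n[2])
  rows <- list(
    cbind(measure = "t2_ms", side = "both",
          reference_range(pooled_bilateral_stats(t2_l, t2_r))),
    cbind(measure = "t2_ms", side = "left", reference_range(t2_l)),
    cbind(measure = "t2_ms", side = "right", reference_range(t2_r)),
    cbind(measure = "volume_cm3", side = "both",
          reference_range(pooled_bilateral_stats(vol_l, vol_r))),
    cbind(measure = "volume_cm3", side = "left", reference_range(vol_l)),
    cbind(measure = "volume_cm3", side = "right", reference_range(vol_r)))
  as_tibble(do.call(rbind, rows))
}

#' Pipeline configuration
#'
#' Collects every tunable of the per-subject measurement chain. All
#' defaults mirror the clinical protocol the package targets: TE 30/119
#' msec, single in-plane erosion, 170 msec CSF cutoff.
#'
#' @param te1,te2 Echo times in msec.
#' @param policy An [roi_policy()].
#' @param t2_max Validity ceiling passed to [fit_t2_map()].
#' @param invert_transform If `TRUE`, supplied transform files are
#'   interpreted as reference-world to mask-world and inverted before use.
#' @param normative Reference-range tibble ([normative_reference()]
#'   layout), or `NULL` to skip flagging.
#' @param icv_model An [fit_icv_model()] for volume correction, or `NULL`
#'   to report raw volumes only.
#' @param classifier_left,classifier_right Optional [fit_hs_classifier()]
#'   models applied to each side's (corrected volume, T2) features.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(te1 = 30, te2 = 119, policy = roi_policy(),
                            t2_max = 3000, invert_transform = FALSE,
                            normative = normative_reference(),
                            icv_model = NULL,
                            classifier_left = NULL, classifier_right = NULL) {
  structure(list(te1 = te1, te2 = te2, policy = policy, t2_max = t2_max,
                 invert_transform = invert_transform, normative = normative,
                 icv_model = icv_model,
                 classifier_left = classifier_left,
                 classifier_right = classifier_right),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `te1`, `te2`, `csf_threshold`,
#' `erosion_iterations`, `erosion_mode`, `min_voxels`, `t2_max`,
#' `invert_transform`. Unspecified keys keep package defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pol <- roi_policy(
    erosion_iterations = cfg$erosion_iterations %||% 1L,
    erosion_mode = cfg$erosion_mode %||% "in-plane-2D",
    csf_threshold = cfg$csf_threshold %||% 170,
    min_voxels = cfg$min_voxels %||% 20L)
  pipeline_config(te1 = cfg$te1 %||% 30, te2 = cfg$te2 %||% 119,
                  policy = pol, t2_max = cfg$t2_max %||% 3000,
                  invert_transform = isTRUE(cfg$invert_transform))
}

stage <- function(name, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    ht2_abort(sprintf("[subject %s, stage %s] %s", subject_id, name,
                      conditionMessage(e)),
              "hippot2_error_stage",
              stage = name, subject_id = subject_id, parent = e)
  })
}

range_flag <- function(value, lower, upper) {
  dplyr::case_when(is.na(value) ~ NA_character_,
                   value < lower ~ "low",
                   value > upper ~ "high",
                   TRUE ~ "within")
}

#' Run the automated measurement pipeline on one subject
#'
#' Executes the full chain: read the dual-echo pair, fit the T2 map,
#' resample the hippocampal segmentation through the rigid transform onto
#' the T2 grid, erode, CSF-exclude, summarize per side, compute the raw
#' (and, when an ICV model and ICV are supplied, corrected) hippocampal
#' volumes on the segmentation's native grid, flag measurements against
#' the normative reference ranges, and optionally apply the side-wise
#' classifiers.
#'
#' @param record A named list (or one-row data frame) with fields
#'   `subject_id`, `s1`, `s2`, `seg` (NIfTI paths), optional `transform`
#'   (plain-text 4x4; identity if missing/`NA`), optional `icv` (cm^3),
#'   optional `te1`/`te2` overriding the config.
#' @param config A [pipeline_config()].
#' @return A tibble, one row per measured side: ROI summary columns plus
#'   `raw_volume_cm3`, `corrected_volume_cm3`, `t2_flag`, `volume_flag`,
#'   and `p_pathologic` when a classifier is configured.
#' @export
run_subject <- function(record, config = pipeline_config()) {
  record <- as.list(record)
  sid <- record$subject_id %||% "unknown"
  te1 <- record$te1 %||% config$te1
  te2 <- record$te2 %||% config$te2

  s1 <- stage("read_s1", sid, read_nifti(record$s1))
  s2 <- stage("read_s2", sid, read_nifti(record$s2))
  seg <- stage("read_segmentation", sid, read_nifti(record$seg, label = TRUE))
  tr <- if (is.null(record$transform) || is.na(record$transform)) {
    diag(4)
  } else {
    stage("read_transform", sid, read_transform(record$transform))
  }
  acq <- stage("dual_echo", sid, dual_echo_acquisition(s1, s2, te1, te2))
  t2map <- stage("fit_t2_map", sid, fit_t2_map(acq, t2_max = config$t2_max))
  seg_t2 <- stage("resample", sid,
                  resample_mask(seg, tr, reference = s1,
                                invert = config$invert_transform))
  meas <- stage("roi_measurement", sid,
                measure_hippocampal_t2(seg_t2, t2map, config$policy))

  vols <- stage("volumetry", sid, mask_volume(seg))
  meas$raw_volume_cm3 <- vols$volume_cm3[match(meas$label, vols$label)]
  icv <- record$icv %||% NA_real_
  meas$corrected_volume_cm3 <-
    if (!is.null(config$icv_model) && is.finite(icv)) {
      correct_volume(meas$raw_volume_cm3, icv, config$icv_model)
    } else {
      meas$raw_volume_cm3
    }
  meas <- dplyr::mutate(meas, subject_id = sid, .before = 1)

  if (!is.null(config$normative)) {
    nr <- config$normative
    pick <- function(measure) nr[nr$measure == measure & nr$side == "both", ]
    t2r <- pick("t2_ms")
    vr <- pick("volume_cm3")
    meas$t2_flag <- range_flag(meas$mean_t2_ms, t2r$lower, t2r$upper)
    meas$volume_flag <- range_flag(meas$corrected_volume_cm3, vr$lower, vr$upper)
  }
  if (!is.null(config$classifier_left) || !is.null(config$classifier_right)) {
    meas$p_pathologic <- NA_real_
  }
  for (side in c("left", "right")) {
    mdl <- config[[paste0("classifier_", side)]]
    i <- which(meas$structure == side)
    if (!is.null(mdl) && length(i) == 1L) {
      feats <- tibble(volume_cm3 = meas$corrected_volume_cm3[i],
                      t2_ms = meas$mean_t2_ms[i])
      meas$p_pathologic[i] <-
        classify_hippocampi(mdl, feats)$p_pathologic
    }
  }
  meas
}

#' Run the pipeline and cohort statistics over a subject manifest
#'
#' Per-subject measurement ([run_subject()]) over a manifest, followed by
#' the cohort-level analyses: group summary table with equal-variance
#' t-tests against controls, reference ranges refit from the manifest's
#' controls (falling back to the configured normative table when there are
#' no controls), side-wise (volume, T2) logistic classifiers, and, when
#' repeat-scan paths (`s1_repeat`, `s2_repeat`) are present, Bland-Altman
#' scan-rescan agreement of the automated T2 measurement.
#'
#' In batch mode a failing subject is reported and skipped, not fatal.
#'
#' @param manifest A data frame, one row per subject, with the
#'   [run_subject()] fields plus `group`.
#' @param config A [pipeline_config()].
#' @return A list of class `hs_cohort_results`: `reports` (per-hippocampus
#'   tibble), `failures` (tibble of skipped subjects), `group_table`,
#'   `reference_ranges`, `classifiers`, `agreement` (or `NULL`).
#' @export
run_cohort <- function(manifest, config = pipeline_config()) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  reports <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- as.list(manifest[i, ])
    res <- tryCatch(run_subject(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(subject_id = rec$subject_id %||% sprintf("row_%d", i),
               error = conditionMessage(res))
    } else {
      res$group <- rec$group %||% NA_character_
      reports[[length(reports) + 1L]] <- res
    }
  }
  reports <- dplyr::bind_rows(reports)
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble(subject_id = character(), error = character())
  if (nrow(reports) == 0L) {
    ht2_abort("no subject in the manifest could be processed",
              "hippot2_error_empty_cohort")
  }

  feats <- tibble(subject_id = reports$subject_id,
                  group = reports$group,
                  side = reports$structure,
                  volume_cm3 = reports$corrected_volume_cm3,
                  t2_ms = reports$mean_t2_ms)

  group_table <- cohort_group_table(feats)
  ranges <- cohort_reference_ranges(feats, config)
  classifiers <- list()
  for (side in c("left", "right")) {
    sf <- cohort_side_features(feats, side)
    if (length(unique(sf$pathologic)) == 2L && min(table(sf$pathologic)) >= 2L) {
      classifiers[[side]] <- fit_hs_classifier(sf)
    }
  }

  agreement <- NULL
  if (all(c("s1_repeat", "s2_repeat") %in% names(manifest))) {
    has_rep <- !is.na(manifest$s1_repeat) & !is.na(manifest$s2_repeat)
    if (any(has_rep)) {
      rep_manifest <- manifest[has_rep, ]
      rep_manifest$s1 <- rep_manifest$s1_repeat
      rep_manifest$s2 <- rep_manifest$s2_repeat
      rep_reports <- dplyr::bind_rows(lapply(seq_len(nrow(rep_manifest)), function(j) {
        run_subject(as.list(rep_manifest[j, ]), config)
      }))
      key <- paste(reports$subject_id, reports$structure)
      rep_key <- paste(rep_reports$subject_id, rep_reports$structure)
      common <- intersect(key, rep_key)
      agreement <- paired_comparison(
        reports$mean_t2_ms[match(common, key)],
        rep_reports$mean_t2_ms[match(common, rep_key)])
    }
  }

  structure(list(reports = reports, failures = failures,
                 group_table = group_table, reference_ranges = ranges,
                 classifiers = classifiers, agreement = agreement,
                 features = feats),
            class = "hs_cohort_results")
}

cohort_group_table <- function(feats) {
  has_controls <- any(feats$group == "control", na.rm = TRUE)
  long <- tidyr::pivot_longer(feats, c("volume_cm3", "t2_ms"),
                              names_to = "measure", values_to = "value")
  tab <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$side, .data$measure),
    mean = mean(.data$value), sd = sd(.data$value), n = dplyr::n(),
    .groups = "drop")
  if (has_controls) {
    tab$p_vs_control <- purrr::pmap_dbl(tab, function(group, side, measure, ...) {
      if (group == "control") return(NA_real_)
      a <- long$value[long$group == group & long$side == side &
                        long$measure == measure]
      b <- long$value[long$group == "control" & long$side == side &
                        long$measure == measure]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      # degenerate comparisons (zero spread, equal means) report NA
      tryCatch(two_sample_t(a, b)$p_value,
               hippot2_error_degenerate_t = function(e) NA_real_)
    })
  }
  tab
}

cohort_reference_ranges <- function(feats, config) {
  ctrl <- feats[feats$group == "control" & !is.na(feats$group), ]
  if (nrow(ctrl) < 4L) return(config$normative)
  wide <- tidyr::pivot_wider(ctrl, id_cols = "subject_id",
                             names_from = "side",
                             values_from = c("volume_cm3", "t2_ms"))
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2L) return(config$normative)
  gs <- function(x) group_stats(mean(x), sd(x), length(x))
  rows <- list(
    cbind(measure = "t2_ms", side = "both",
          reference_range(pooled_bilateral_stats(gs(wide$t2_ms_left),
                                                 gs(wide$t2_ms_right)))),
    cbind(measure = "t2_ms", side = "left", reference_range(gs(wide$t2_ms_left))),
    cbind(measure = "t2_ms", side = "right", reference_range(gs(wide$t2_ms_right))),
    cbind(measure = "volume_cm3", side = "both",
          reference_range(pooled_bilateral_stats(gs(wide$volume_cm3_left),
                                                 gs(wide$volume_cm3_right)))),
    cbind(measure = "volume_cm3", side = "left",
          reference_range(gs(wide$volume_cm3_left))),
    cbind(measure = "volume_cm3", side = "right",
          reference_range(gs(wide$volume_cm3_right))))
  as_tibble(do.call(rbind, rows))
}

#' @export
print.hs_cohort_results <- function(x, ...) {
  cat(sprintf("<hs_cohort_results> %d hippocampi from %d subjects (%d failed)\n",
              nrow(x$reports), length(unique(x$reports$subject_id)),
              nrow(x$failures)))
  print(x$group_table)
  invisible(x)
}
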