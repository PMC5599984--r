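#' Default cohort group parameters
#'
#' Group-level means and SDs of ICV-corrected hippocampal volume (cm^3)
#' and automated hippocampal T2 (msec) per side, for a representative
#' refractory-TLE study population: 50 healthy controls, 27 left HS, 18
#' right HS and 5 bilateral HS subjects. These parameters drive the
#' synthetic cohort generator and the shipped normative reference ranges.
#'
#' @return A tibble: `group`, `n`, `side`, `vol_mean`, `vol_sd`,
#'   `t2_mean`, `t2_sd`.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~group,         ~n,  ~side,   ~vol_mean, ~vol_sd, ~t2_mean, ~t2_sd,
    "control",      50L, "left",  3.02,      0.28,    115.5,    4.11,
    "control",      50L, "right", 3.04,      0.25,    116.8,    3.60,
    "left_hs",      27L, "left",  2.05,      0.30,    127.7,    8.18,
    "left_hs",      27L, "right", 2.95,      0.30,    119.5,    3.00,
    "right_hs",     18L, "left",  2.96,      0.28,    118.1,    4.49,
    "right_hs",     18L, "right", 2.20,      0.28,    128.1,    7.05,
    "bilateral_hs", 5L,  "left",  2.07,      0.17,    126.8,    8.80,
    "bilateral_hs", 5L,  "right", 2.26,      0.29,    129.9,    4.91)
}

#' Generate a synthetic (volume, T2) cohort
#'
#' Draws per-hippocampus ICV-corrected volume and mean T2 from the
#' group-wise Gaussians of `params`. Within a subject, left and right
#' values of the same measure are correlated at `cross_side_cor`
#' (bivariate normal); volume and T2 are drawn independently. Generation
#' is a pure function of `seed`.
#'
#' @param params Group parameter tibble in the [default_group_params()]
#'   layout; `n` may be overridden per group.
#' @param cross_side_cor Left-right correlation of each measure within a
#'   subject (default 0.3).
#' @param seed Optional integer seed.
#' @return A tibble: `subject_id`, `group`, `side`, `volume_cm3`, `t2_ms`.
#' @export
generate_cohort <- function(params = default_group_params(),
                            cross_side_cor = 0.3, seed = NULL) {
  stopifnot(abs(cross_side_cor) <= 1)
  run <- function() {
    purrr::map_dfr(unique(params$group), function(g) {
      p <- params[params$group == g, ]
      stopifnot(nrow(p) == 2L)
      p <- p[match(c("left", "right"), p$side), ]
      n <- p$n[1]
      stopifnot(n >= 1L)
      R <- matrix(c(1, cross_side_cor, cross_side_cor, 1), 2)
      draw2 <- function(means, sds) {
        S <- diag(sds) %*% R %*% diag(sds)
        # mvrnorm drops to a vector for n = 1
        matrix(MASS::mvrnorm(n, mu = means, Sigma = S), ncol = 2)
      }
      vols <- draw2(p$vol_mean, p$vol_sd)
      t2s <- draw2(p$t2_mean, p$t2_sd)
      tibble(
        subject_id = rep(sprintf("%s_%03d", g, seq_len(n)), times = 2),
        group = g,
        side = rep(c("left", "right"), each = n),
        volume_cm3 = c(vols[, 1], vols[, 2]),
        t2_ms = c(t2s[, 1], t2s[, 2]))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pathology labels for one side's hippocampi
#'
#' Labeling convention for the side-wise classifiers: a left hippocampus
#' is pathologic when the subject has left or bilateral HS (mirrored for
#' the right side); controls and contralateral-HS hippocampi are
#' non-pathologic.
#'
#' @param group Character vector of group memberships (`"control"`,
#'   `"left_hs"`, `"right_hs"`, `"bilateral_hs"`).
#' @param side `"left"` or `"right"`: which hippocampus is being labeled.
#' @return Logical vector, `TRUE` = pathologic.
#' @export
pathologic_label <- function(group, side = c("left", "right")) {
  side <- match.arg(side)
  group %in% c(paste0(side, "_hs"), "bilateral_hs")
}

#' One side's feature table with pathology labels
#'
#' @param cohort A [generate_cohort()] tibble (or any tibble with `group`,
#'   `side`, `volume_cm3`, `t2_ms`).
#' @param side `"left"` or `"right"`.
#' @return The side's rows with a logical `pathologic` column appended.
#' @export
cohort_side_features <- function(cohort, side = c("left", "right")) {
  side <- match.arg(side)
  out <- cohort[cohort$side == side, ]
  out$pathologic <- pathologic_label(out$group, side)
  as_tibble(out)
}

#' Training classification rate of the (volume, T2) classifier
#'
#' Fits the side-wise logistic classifier on a cohort and reports the
#' fraction of that side's hippocampi correctly classified at the 0.5
#' threshold (training classification, matching how such classifiers are
#' conventionally reported for these cohorts).
#'
#' @inheritParams cohort_side_features
#' @param features Feature columns (default volume + T2).
#' @return Training accuracy in `[0, 1]`.
#' @export
classification_rate <- function(cohort, side = c("left", "right"),
                                features = c("volume_cm3", "t2_ms")) {
  feats <- cohort_side_features(cohort, side)
  model <- fit_hs_classifier(feats, features = features)
  pred <- classify_hippocampi(model, feats)
  mean(pred$pathologic_pred == feats$pathologic)
}

#' Classification rates over repeated synthetic cohorts
#'
#' Draws `n_seeds` cohorts and records the side-wise training
#' classification rate of the combined (volume, T2) model for each.
#'
#' @param n_seeds Number of cohort replicates (default 200).
#' @param params,cross_side_cor Passed to [generate_cohort()].
#' @param features Feature columns for the classifier.
#' @param seed Master seed; cohort `i` uses `seed + i`.
#' @return A tibble: `replicate`, `side`, `accuracy`.
#' @export
classification_study <- function(n_seeds = 200, params = default_group_params(),
                                 cross_side_cor = 0.3,
                                 features = c("volume_cm3", "t2_ms"),
                                 seed = 1L) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cohort <- generate_cohort(params, cross_side_cor, seed = seed + i)
    tibble(replicate = i,
           side = c("left", "right"),
           accuracy = c(classification_rate(cohort, "left", features),
                        classification_rate(cohort, "right", features)))
  })
}
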