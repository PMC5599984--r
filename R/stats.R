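#' Group summary statistics
#'
#' @param mean Group mean.
#' @param sd Group SD (n-1 denominator).
#' @param n Group size (>= 2).
#' @return A `group_stats` list.
#' @export
group_stats <- function(mean, sd, n) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "group_stats")
}

#' Pool left and right group statistics into bilateral statistics
#'
#' Reconstructs the mean and SD of the concatenated left+right sample from
#' per-side moments (equal per-side n). The pooled variance is the exact
#' Bessel-corrected variance of the concatenation:
#' `[(n-1)(s_L^2 + s_R^2) + n((m_L - m)^2 + (m_R - m)^2)] / (2n - 1)`.
#' This is the only pooling consistent with computing a single reference
#' range over both sides' measurements.
#'
#' @param left,right `group_stats` for each side, equal `n`.
#' @return A `group_stats` for the pooled bilateral sample (size `2n`).
#' @export
pooled_bilateral_stats <- function(left, right) {
  stopifnot(inherits(left, "group_stats"), inherits(right, "group_stats"))
  if (left$n != right$n) {
    ht2_abort("bilateral pooling requires equal per-side n", "hippot2_error_pooling")
  }
  n <- left$n
  m <- (left$mean + right$mean) / 2
  v <- ((n - 1) * (left$sd^2 + right$sd^2) +
          n * ((left$mean - m)^2 + (right$mean - m)^2)) / (2 * n - 1)
  group_stats(m, sqrt(v), 2L * n)
}

#' Normative reference range: mean +/- 1.96 SD
#'
#' The normative interval from healthy controls; measurements outside it
#' are flagged abnormal (low volume, high T2 being the hippocampal
#' sclerosis pattern).
#'
#' @param stats A `group_stats`.
#' @param k Multiplier on the SD (default 1.96, the two-sided 95% normal
#'   quantile).
#' @return A one-row tibble: `center`, `sd`, `lower`, `upper`.
#' @export
reference_range <- function(stats, k = 1.96) {
  stopifnot(inherits(stats, "group_stats"))
  tibble(center = stats$mean,
         sd = stats$sd,
         lower = stats$mean - k * stats$sd,
         upper = stats$mean + k * stats$sd)
}

#' Fit the hippocampal (volume, T2) logistic classifier
#'
#' Binary logistic regression of pathologic status on ICV-corrected
#' hippocampal volume and/or hippocampal T2, fitted per side. The fit is
#' maximum likelihood by iteratively reweighted least squares
#' (`stats::glm`, binomial logit; coefficient-change tolerance 1e-8, at
#' most 100 iterations). Perfect separation is reported through the
#' `converged`/`separated` flags with the iteration-cap coefficients still
#' returned.
#'
#' @param data A data frame with the feature columns and the label column.
#' @param features Character vector of feature column names (any subset of
#'   the available features; default both `volume_cm3` and `t2_ms`).
#' @param label Name of the logical/0-1 column marking pathologic
#'   hippocampi (default `"pathologic"`).
#' @return An object of class `hs_classifier`.
#' @export
fit_hs_classifier <- function(data, features = c("volume_cm3", "t2_ms"),
                              label = "pathologic") {
  stopifnot(is.data.frame(data), all(c(features, label) %in% names(data)))
  y <- as.integer(data[[label]])
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    ht2_abort("logistic fit needs at least 2 examples in each class",
              "hippot2_error_single_class")
  }
  df <- data[, features, drop = FALSE]
  df$.y <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    coefficients = coef(fit),
    features = features,
    converged = fit$converged && !separated,
    separated = separated,
    log_likelihood = as.numeric(stats::logLik(fit)),
    fit = fit),
    class = "hs_classifier")
}

#' Classify hippocampi with a fitted (volume, T2) model
#'
#' Logistic probability of pathology with a fixed decision threshold of
#' 0.5 (probabilities >= 0.5 are flagged pathologic).
#'
#' @param model An [fit_hs_classifier()] object.
#' @param newdata Data frame containing the model's feature columns.
#' @return `newdata` with `p_pathologic` and `pathologic_pred` columns
#'   appended, as a tibble.
#' @export
classify_hippocampi <- function(model, newdata) {
  stopifnot(inherits(model, "hs_classifier"))
  if (is.null(model$fit)) {
    ht2_abort("classifier has not been fitted", "hippot2_error_unfitted")
  }
  stopifnot(all(model$features %in% names(newdata)))
  p <- predict(model$fit, newdata = newdata, type = "response")
  out <- as_tibble(newdata)
  out$p_pathologic <- unname(p)
  out$pathologic_pred <- out$p_pathologic >= 0.5
  out
}

#' @export
print.hs_classifier <- function(x, ...) {
  cat(sprintf("<hs_classifier> features: %s; converged: %s%s\n",
              paste(x$features, collapse = " + "),
              x$converged,
              if (x$separated) " (perfect separation)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.hs_classifier <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s),
         estimate = s[, 1],
         std_error = s[, 2],
         statistic = s[, 3],
         p_value = s[, 4])
}

#' @export
glance.hs_classifier <- function(x, ...) {
  y <- x$fit$y
  acc <- mean((x$fit$fitted.values >= 0.5) == (y == 1L))
  tibble(n = length(y),
         training_accuracy = acc,
         log_likelihood = x$log_likelihood,
         converged = x$converged,
         separated = x$separated)
}

#' Two-tailed independent-samples t-test assuming equal variances
#'
#' Pooled-variance t statistic with `n_a + n_b - 2` degrees of freedom,
#' the group-comparison test used throughout the cohort tables.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) + var(b) == 0) {
    if (mean(a) == mean(b)) {
      ht2_abort("t statistic undefined: zero pooled variance with equal means",
                "hippot2_error_degenerate_t")
    }
    return(tibble(t = Inf * sign(mean(a) - mean(b)),
                  df = length(a) + length(b) - 2, p_value = 0,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(t = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_a = mean(a),
         mean_b = mean(b))
}

#' Paired agreement analysis (Bland-Altman + paired t-test)
#'
#' Mean and SD (n-1) of the paired differences `x - y`, limits of
#' agreement at mean +/- 1.96 SD, a two-tailed paired t-test for equality
#' of means, and the Pearson correlation of the two measurement series.
#' Used for scan-rescan reproducibility and method-agreement studies.
#'
#' @param x,y Paired measurements (e.g. scan and rescan), equal length
#'   >= 3.
#' @return An object of class `t2_agreement`: a one-row summary tibble is
#'   returned by [glance.t2_agreement()]; the object stores the pairs for
#'   plotting via [autoplot.t2_agreement()].
#' @export
paired_comparison <- function(x, y) {
  if (length(x) != length(y)) {
    ht2_abort("paired comparison requires equal-length series",
              "hippot2_error_length_mismatch")
  }
  stopifnot(length(x) >= 3)
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  if (s > 0) {
    tt <- t.test(d)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  r <- if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  structure(list(
    mean_diff = m,
    sd_diff = s,
    loa_lower = m - 1.96 * s,
    loa_upper = m + 1.96 * s,
    t_statistic = t_stat,
    p_value = p,
    pearson_r = r,
    n = length(x),
    x = x, y = y),
    class = "t2_agreement")
}

#' @export
print.t2_agreement <- function(x, ...) {
  cat(sprintf(
    "<t2_agreement> n = %d pairs; mean diff %.3g, SD %.3g, LoA [%.3g, %.3g], r = %.3f\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper, x$pearson_r))
  invisible(x)
}

#' @export
glance.t2_agreement <- function(x, ...) {
  tibble(mean_diff = x$mean_diff,
         sd_diff = x$sd_diff,
         loa_lower = x$loa_lower,
         loa_upper = x$loa_upper,
         t_statistic = x$t_statistic,
         p_value = x$p_value,
         pearson_r = x$pearson_r,
         n = x$n)
}
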