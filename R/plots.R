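#' Bland-Altman plot of a paired agreement analysis
#'
#' Difference against pair mean, with the mean difference and the 95%
#' limits of agreement (mean +/- 1.96 SD of differences) drawn as
#' horizontal lines.
#'
#' @param object A [paired_comparison()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.t2_agreement <- function(object, ...) {
  df <- tibble(avg = (object$x + object$y) / 2, diff = object$x - object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "Pair mean", y = "Difference (repeat 1 - repeat 2)",
                  title = "Bland-Altman agreement",
                  subtitle = sprintf("mean diff %.2f, LoA [%.2f, %.2f]",
                                     object$mean_diff, object$loa_lower,
                                     object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Anteroposterior T2 slice profile plot
#'
#' @param object A [slice_profile()] tibble.
#' @param ... Ignored.
#' @return A ggplot (anterior on the left).
#' @export
autoplot.t2_slice_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$position <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_t2_ms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_voxels), alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(x = "Slice (anterior to posterior)", y = "Mean T2 (msec)",
                  size = "Voxels",
                  title = "Hippocampal T2 slice profile") +
    ggplot2::theme_minimal()
}

#' Cohort feature scatter: corrected volume against mean T2
#'
#' The standard two-feature view separating sclerotic from healthy
#' hippocampi: low volume + high T2 marks the pathologic corner.
#'
#' @param cohort A tibble with `group`, `side`, `volume_cm3`, `t2_ms`
#'   (e.g. from [generate_cohort()] or the `features` element of
#'   [run_cohort()] results).
#' @return A ggplot, faceted by side.
#' @export
plot_cohort_features <- function(cohort) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$volume_cm3, y = .data$t2_ms,
                                       colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "Corrected hippocampal volume (cm³)",
                  y = "Mean hippocampal T2 (msec)", colour = "Group") +
    ggplot2::theme_minimal()
}
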