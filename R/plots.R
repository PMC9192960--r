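#' Plot group differences in mean connectivity
#'
#' Dot plot of per-subject mean DEC on the target connection by group, with
#' group means and normal-theory 95% intervals — the standard way a
#' case-control connectivity difference is displayed.
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.pipeline_result <- function(object, ...) {
  tab <- dplyr::filter(object$cohort, !.data$excluded_motion)
  means <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      m = mean(.data$target_dec_mean),
      se = sd(.data$target_dec_mean) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(tab, ggplot2::aes(.data$group, .data$target_dec_mean)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(
      data = means,
      ggplot2::aes(.data$group, .data$m,
                   ymin = .data$m - 1.96 * .data$se,
                   ymax = .data$m + 1.96 * .data$se),
      inherit.aes = FALSE, shape = 3, linewidth = 1) +
    ggplot2::labs(x = NULL, y = sprintf("mean DEC (%s)", object$target))
}

#' Plot the symptom-connectivity association
#'
#' Scatter of symptom score against mean DEC on the target connection for
#' patients, with the least-squares line and its confidence band.
#'
#' @param result A `pipeline_result`.
#' @param symptom Symptom column, default `ybocs`.
#' @return A ggplot.
#' @export
plot_symptom_association <- function(result, symptom = "ybocs") {
  tab <- dplyr::filter(result$cohort, .data$group == "patient",
                       !.data$excluded_motion)
  ggplot2::ggplot(tab, ggplot2::aes(.data$target_dec_mean,
                                    .data[[symptom]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = sprintf("mean DEC (%s)", result$target), y = symptom)
}
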