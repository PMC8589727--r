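#' Plot a prevalence table as point estimates with confidence bars
#'
#' @param prevalence Output of [prevalence_table()] (stratified form).
#' @return A ggplot object: percent prescribed per stratum level with
#'   Wald confidence intervals.
#' @export
plot_prevalence <- function(prevalence) {
  stopifnot(all(c("level", "percent", "ci_low", "ci_high") %in% names(prevalence)))
  ggplot2::ggplot(
    prevalence,
    ggplot2::aes(x = .data$percent, y = .data$level)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$stratum),
      scales = "free_y", space = "free_y"
    ) +
    ggplot2::labs(
      x = "Prescribing prevalence per 100 persons (95% CI)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the joint adherence-by-persistence classification
#'
#' @param joint Output of [joint_classification()] (optionally with a
#'   `landmark` column).
#' @return A stacked-bar ggplot of cell percentages per index drug.
#' @export
plot_joint_classification <- function(joint) {
  stopifnot(all(c("cell", "percent") %in% names(joint)))
  p <- ggplot2::ggplot(
    joint,
    ggplot2::aes(x = .data$index_drug, y = .data$percent, fill = .data$cell)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "% of landmark-eligible patients", fill = NULL
    ) +
    ggplot2::theme_minimal()
  if ("landmark" %in% names(joint)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$landmark))
  }
  p
}

#' Forest plot of model effect estimates
#'
#' @param x A `thromb_fit` ([fit_nonadherence_model()] and friends).
#' @param object,... Standard autoplot arguments.
#' @return A ggplot forest plot of the tidied estimates on a log scale.
#' @export
plot_effects <- function(x) {
  td <- tidy(x)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = x$effect_label, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_effects
#' @method autoplot thromb_fit
#' @export
autoplot.thromb_fit <- function(object, ...) plot_effects(object)
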