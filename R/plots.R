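#' Plot a fitted aging trajectory
#'
#' Scatter of the ALPS index against the aging index with the fitted OLS
#' line and its slope/r/p annotation.
#'
#' @param object A [fit_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  lab <- sprintf(
    "slope = %.3g, r = %.3f, p = %.3g", object$slope, object$r, object$p
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = paste("aging index:", object$kind), y = "DTI-ALPS index",
      title = if (is.na(object$group)) lab else paste0(object$group, ": ", lab)
    ) +
    ggplot2::theme_minimal()
}

#' Group trajectories of ALPS against a structure's brain-PAD
#'
#' Overlays the control and HIV groups with their separate regression lines,
#' the visual counterpart of the slope-equality test.
#'
#' @param cohort Subject table (see [generate_cohort()]).
#' @param structure Structure label whose `pred_age_<structure>` column
#'   supplies the brain-PAD.
#' @return A ggplot object.
#' @export
plot_group_trajectories <- function(cohort, structure) {
  cohort <- tibble::as_tibble(cohort)
  col <- paste0("pred_age_", structure)
  if (!col %in% names(cohort)) {
    abort(sprintf("No column '%s' in the cohort table.", col))
  }
  df <- tibble::tibble(
    pad = cohort[[col]] - cohort$age,
    alps = cohort$alps,
    group = cohort$group
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pad, y = .data$alps, colour = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c(hc = "grey25", hiv = "firebrick")) +
    ggplot2::labs(
      x = sprintf("brain-PAD, %s (years)", structure),
      y = "DTI-ALPS index", colour = "group"
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of brain-PADs by group
#'
#' @param cohort Subject table with `pred_age_*` columns.
#' @return A ggplot object.
#' @export
plot_pad_by_group <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  pads <- compute_brain_pad(cohort) |>
    dplyr::mutate(group = cohort$group) |>
    tidyr::pivot_longer(
      dplyr::starts_with("pad"),
      names_to = "structure", values_to = "pad", names_prefix = "pad_"
    )
  ggplot2::ggplot(pads, ggplot2::aes(
    x = .data$structure, y = .data$pad, fill = .data$group
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(hc = "white", hiv = "firebrick")) +
    ggplot2::labs(x = NULL, y = "brain-PAD (years)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
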