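# ggplot2 helpers for the result types.

#' Plot a trajectory metric time series
#'
#' @param series A metric tibble (`time`, `value`, `metric`) from
#'   [rmsd_series()], [hbond_count_series()] or [sasa_series()]; series can
#'   be row-bound with a `label` column for multi-trace plots.
#' @return A ggplot object.
#' @export
plot_metric_series <- function(series) {
  aes <- if ("label" %in% names(series)) {
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$time, y = .data$value)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = unique(series$metric)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param profile Output of [rmsf_profile()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue index", y = unique(profile$metric)[1]) +
    ggplot2::theme_minimal()
}

#' Violin summary of one or more metric series
#'
#' @param series A metric tibble with `value` and optionally `label`.
#' @return A ggplot object.
#' @export
plot_distribution_violin <- function(series) {
  if (!"label" %in% names(series)) series$label <- unique(series$metric)[1]
  ggplot2::ggplot(series, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.four_pl_fit <- function(object, n_curve = 200, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble::tibble(
    concentration = exp(seq(log(rng[1]), log(rng[2]), length.out = n_curve))
  )
  grid$activity <- predict(object, grid)
  p <- ggplot2::ggplot(object$data,
    ggplot2::aes(x = .data$concentration, y = .data$activity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (uM)", y = "activity (%)",
      title = if (!is.na(object$compound)) object$compound else NULL,
      subtitle = sprintf("IC50 = %.2f uM, r^2 = %.4f", object$ic50,
        object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$ic50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ic50,
      linetype = "dashed", colour = "grey40")
  }
  p
}
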