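#' Noise-versus-mean diagnostic plot
#'
#' The standard CV-squared (or Fano) versus mean scatter on log10 axes,
#' coloured by condition when available. Poisson-limited genes fall on the
#' `cv2 = 1/mean` line; bursty genes sit above it.
#'
#' @param summary A noise summary tibble from [noise_summary()].
#' @param metric `"cv2"` or `"fano"`.
#'
#' @return A ggplot object.
#' @export
plot_noise_mean <- function(summary, metric = c("cv2", "fano")) {
  metric <- match.arg(metric)
  df <- dplyr::filter(summary, !.data$undefined)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$mean, y = .data[[metric]])
  ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "mean expression",
      y = if (metric == "cv2") expression(CV^2) else "Fano factor"
    ) +
    ggplot2::theme_classic()
  if ("condition" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$condition),
      alpha = 0.7
    ) +
      ggplot2::scale_colour_manual(
        values = c(control = "grey30", treated = "firebrick")
      )
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  if (metric == "cv2") {
    p <- p + ggplot2::geom_function(
      fun = function(x) 1 / x, linetype = "dashed", colour = "grey60"
    )
  }
  p
}

#' Burst-parameter reciprocity plot
#'
#' Scatter of log2 fold change in burst size against log2 fold change in
#' burst frequency, with the homeostatic anti-diagonal (slope -1 through the
#' origin) as a guide and, optionally, the fitted regression line.
#'
#' @param fc Tibble from [burst_fold_changes()].
#' @param fit Optional `"reciprocity_fit"` from [reciprocity_regression()].
#'
#' @return A ggplot object.
#' @export
plot_reciprocity <- function(fc, fit = NULL) {
  df <- dplyr::filter(
    fc, is.finite(.data$log2_d_burst_frequency),
    is.finite(.data$log2_d_burst_size)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_d_burst_frequency, y = .data$log2_d_burst_size,
    colour = .data$gene_id
  )) +
    ggplot2::geom_abline(
      slope = -1, intercept = 0, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(log[2] ~ Delta * "burst frequency"),
      y = expression(log[2] ~ Delta * "burst size"),
      colour = "gene"
    ) +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      slope = fit$slope, intercept = fit$intercept, colour = "black"
    )
  }
  p
}
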