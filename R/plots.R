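# ggplot2 visualizations for the main result types.

#' @export
autoplot.contact_matrix <- function(object, log_scale = TRUE, ...) {
  df <- tidy(object)
  df2 <- df[df$bin1 != df$bin2, c("chrom", "bin2", "bin1", "count")]
  names(df2) <- c("chrom", "bin1", "bin2", "count")
  df <- bind_rows(df, df2)
  if (log_scale) df$count <- log10(df$count + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin1, y = .data$bin2,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = if (log_scale) "log10(n+1)" else
                                   "count") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$chrom, x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}

#' Plot a median boundary profile
#'
#' @param curve Output of [boundary_profile()] (optionally several,
#'   row-bound with a `sample` column).
#' @return A ggplot object.
#' @export
plot_boundary_profile <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$offset / 1e3,
                                           y = .data$value))
  if ("sample" %in% names(curve)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$sample))
  } else {
    p <- p + ggplot2::geom_line(color = "firebrick")
  }
  p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from boundary (kb)",
                  y = "median signal") +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome effect size against normalized copy number
#'
#' @param fit A [regress_effect_size()] result (`dosage_fit`).
#' @return A ggplot object.
#' @export
plot_effect_size <- function(fit) {
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$norm_copy,
                                         y = .data$mean_d)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         color = "grey50") +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$chrom), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = "normalized copy number", y = "Cohen's d") +
    ggplot2::theme_minimal()
}

#' Plot smoothed gene-pair correlation curves
#'
#' @param curves Output of [smooth_curves()].
#' @return A ggplot object.
#' @export
plot_pair_correlation_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$distance / 1e6,
                                       y = .data$rho_smooth,
                                       color = .data$class)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(same_tad = "firebrick",
                                           different_tad = "steelblue",
                                           random_domain = "grey50")) +
    ggplot2::labs(x = "TSS distance (Mb)",
                  y = "Spearman correlation (smoothed)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param de Output of [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_adj),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey60"),
                                name = "BH <= 0.05") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
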