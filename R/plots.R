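#' Quantile plot of corrected frequency differences
#'
#' The correction diagnostic: sorted corrected deltas against the
#' standardized quantile axis. A correctly total-corrected null cohort
#' passes through delta = 0 at the 0 quantile point (the mean of the
#' difference distribution).
#'
#' @param diagnostic Output of [delta_quantile_diagnostic()].
#' @return A ggplot.
#' @export
plot_delta_quantiles <- function(diagnostic) {
  ggplot2::ggplot(diagnostic, ggplot2::aes(x = .data$quantile, y = .data$delta)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "Standard normal quantile",
                  y = "Corrected frequency difference (delta)") +
    ggplot2::theme_minimal()
}

#' Normality quantile plot of log10 intensities
#'
#' @param qq Output of [qq_normality()].
#' @return A ggplot with the ideal Gaussian reference line dashed in red.
#' @export
plot_qq_normality <- function(qq) {
  m <- mean(qq$sample); s <- sd(qq$sample)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(intercept = m, slope = s, colour = "red",
                         linetype = "dashed") +
    ggplot2::labs(x = "Normal theoretical quantile",
                  y = "Log10 precursor intensity") +
    ggplot2::theme_minimal()
}

#' Per-treatment intensity distributions for one gene
#'
#' Box plot of log10 precursor intensities across treatments with the
#' Tukey-Kramer compact letters printed above each box.
#'
#' @param object A `gene_anova`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_anova
#' @export
autoplot.gene_anova <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$Treatment_ID),
                                       y = .data$log10_intensity)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Treatment", y = "Log10 precursor intensity",
                  title = object$gene_symbol) +
    ggplot2::theme_minimal()
  s <- object$summaries
  if (!is.null(s$letters)) {
    lab <- s |> mutate(y = max(d$log10_intensity) + 0.1)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = factor(.data$treatment_id), y = .data$y,
                   label = .data$letters),
      inherit.aes = FALSE, size = 3
    )
  }
  p
}

#' Chi-square versus corrected delta for one contrast
#'
#' @param object A [chi_square_contrast()] tibble (optionally with selection
#'   flags).
#' @param chi2_min,delta_min Thresholds drawn as reference lines.
#' @return A ggplot.
#' @export
plot_contrast <- function(object, chi2_min = 15, delta_min = 15) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$chi2)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = chi2_min, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = delta_min, linetype = "dotted") +
    ggplot2::labs(x = "Corrected frequency difference (delta)",
                  y = "Pseudocount chi-square") +
    ggplot2::theme_minimal()
}
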