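# Result-type plots. Each returns a ggplot object; nothing is drawn to a
# device as a side effect.

#' Volcano plot of differential translation
#'
#' @param object A [differential_translation()] result.
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 p, points coloured by
#'   class.
#' @method autoplot ribo_differential
#' @export
autoplot.ribo_differential <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.01
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p, colour = .data$class)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", unchanged = "grey60")
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = expression(-log[10] ~ p),
      colour = NULL, title = "Differential translation"
    )
}

#' @rdname autoplot.ribo_differential
#' @export
plot_volcano <- function(object, ...) autoplot.ribo_differential(object, ...)

#' Bar plot of per-timepoint bulk translation with replicate SD
#'
#' @param factors A [scale_factors()] result (footprint assay).
#' @return A ggplot of relative bulk translation per timepoint.
#' @export
plot_bulk_translation <- function(factors) {
  bulk <- bulk_translation(factors)
  ggplot2::ggplot(
    bulk,
    ggplot2::aes(x = .data$timepoint, y = .data$bulk_translation)
  ) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$bulk_translation - .data$sd,
        ymax = .data$bulk_translation + .data$sd
      ),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL, y = "relative bulk translation",
      title = "Spike-normalized bulk translation"
    )
}

#' Scatter plot of condition-mean expression between two timepoints
#'
#' Log-log comparison of per-gene mRNA TPM between two conditions, with the
#' identity line; the tabular analogue of a between-timepoint correlation
#' panel.
#'
#' @param tpm A TPM table with `gene`, `timepoint`, `tpm`.
#' @param timepoint_a,timepoint_b Conditions to compare.
#' @param floor Genes below this TPM in either condition are dropped from
#'   the plot.
#' @return A ggplot.
#' @export
plot_expression_correlation <- function(tpm, timepoint_a, timepoint_b,
                                        floor = 1) {
  wide <- tpm |>
    filter(.data$timepoint %in% c(timepoint_a, timepoint_b)) |>
    group_by(.data$gene, .data$timepoint) |>
    summarise(tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "tpm") |>
    filter(.data[[timepoint_a]] >= floor, .data[[timepoint_b]] >= floor)
  r2 <- stats::cor(log10(wide[[timepoint_a]]), log10(wide[[timepoint_b]]))^2
  ggplot2::ggplot(
    wide,
    ggplot2::aes(x = .data[[timepoint_a]], y = .data[[timepoint_b]])
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_abline(
      slope = 1, intercept = 0, colour = "#b2182b", linetype = "dashed"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste(timepoint_a, "TPM"), y = paste(timepoint_b, "TPM"),
      title = sprintf("Expression correlation (R² = %.2f)", r2)
    )
}
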