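#' Volcano plot of differential methylation results
#'
#' Effect size (difference in mean percent methylation, cases minus
#' controls) against -log10 p-value, coloured by FDR significance.
#'
#' @param results An `ewas_result` tibble from [run_ewas()].
#' @param fdr_level Highlight threshold on `fdr_q`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, fdr_level = 0.05) {
  d <- dplyr::mutate(as_tibble(results),
                     significant = .data$fdr_q < fdr_level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_percent,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("FDR < %g", fdr_level)) +
    ggplot2::labs(x = "Difference in mean percent methylation (cases - controls)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Module-trait relationship heatmap
#'
#' Tile map of eigengene-trait correlations with the correlation and
#' p-value printed in each cell, mirroring the conventional
#' module-trait matrix.
#'
#' @param module_trait Tibble from [module_trait_association()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(module_trait) {
  d <- dplyr::mutate(as_tibble(module_trait),
                     label = sprintf("%.2f\n(%.1g)", .data$correlation,
                                     .data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$module,
                                  fill = .data$correlation)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Soft-threshold scan plot
#'
#' Signed scale-free fit index and mean connectivity against the
#' candidate soft-threshold powers.
#'
#' @param scan Tibble from [soft_threshold_scan()].
#' @param r2_target Reference line for an acceptable fit.
#' @return A ggplot object.
#' @export
plot_soft_threshold <- function(scan, r2_target = 0.8) {
  d <- tidyr::pivot_longer(as_tibble(scan),
                           c("r_squared", "mean_k"),
                           names_to = "panel", values_to = "value")
  d$panel <- factor(d$panel, levels = c("r_squared", "mean_k"),
                    labels = c("signed scale-free fit R^2",
                               "mean connectivity"))
  ref <- tibble(panel = factor("signed scale-free fit R^2",
                               levels = levels(d$panel)),
                yintercept = r2_target)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = 2, colour = "red") +
    ggplot2::geom_text(ggplot2::aes(label = .data$power), size = 3) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "soft threshold (power)", y = NULL) +
    ggplot2::theme_minimal()
}
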