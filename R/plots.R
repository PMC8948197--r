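# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_jitter geom_line
#'   geom_abline geom_tile labs theme_minimal scale_fill_gradient2 coord_equal
#' @export
ggplot2::autoplot

#' @export
#' @rdname imflux_plots
#' @name imflux_plots
#' @title Plots for imflux result objects
#' @description `autoplot()` draws a boxplot of the IM-Index by group
#'   (`imflux_index`), a ROC curve with the chance diagonal (`imflux_roc`),
#'   or a sample-by-pathway flux heatmap (`imflux_flux`).
#' @param object A result object.
#' @param ... Unused.
autoplot.imflux_index <- function(object, ...) {
  df <- as_tibble(object)
  if (!"group" %in% names(df)) {
    stop_config("IM-Index table has no group column; pass labels to compute_im_index()")
  }
  ggplot(df, aes(x = .data$group, y = .data$im_index, fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    labs(x = NULL, y = "IM-Index") +
    theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' @export
#' @rdname imflux_plots
autoplot.imflux_roc <- function(object, ...) {
  pts <- tidy(object)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci_low, object$ci_high)) +
    theme_minimal()
}

#' @export
#' @rdname imflux_plots
autoplot.imflux_flux <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"sample_id",
                              names_to = "pathway_id", values_to = "flux")
  ggplot(long, aes(x = .data$pathway_id, y = .data$sample_id,
                   fill = .data$flux)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "Pathway", y = "Sample", fill = "Flux") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
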