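# ggplot2 helpers for the main result types.

#' Density plot of paralog pair correlations against a random-pair null
#'
#' @param records Output of [pair_coexpression()].
#' @param null Optional output of [random_pair_null()]; drawn dashed.
#' @return A ggplot object.
#' @export
plot_pair_correlations <- function(records, null = NULL) {
  p <- ggplot2::ggplot(records[!is.na(records$R), ],
                       ggplot2::aes(x = .data$R)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Pearson R (paralog pairs)", y = "Density")
  if (!is.null(null)) {
    p <- p + ggplot2::geom_density(data = null[!is.na(null$R), ],
                                   linetype = 2, colour = "red3")
  }
  p
}

#' Scatter plot for a content-variability relation
#'
#' @param object A `cv_relation` from [content_variability_relation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_relation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$paralog_content,
                               y = .data$variability)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3") +
    ggplot2::labs(x = "Paralog content", y = "Complex variability (1 - R)",
                  subtitle = sprintf("R = %.2f, p = %.2g",
                                     object$estimate, object$p_value))
}

#' Heatmap of conserved paralog-ratio changes across comparisons
#'
#' Tiles show the oriented per-comparison log2 ratio differences of the
#' pairs called conserved; unquantified slots are grey.
#'
#' @param object A `conserved_pairs` object from [conserved_signature()].
#' @param conserved_only Show only conserved pairs (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conserved_pairs <- function(object, conserved_only = TRUE, ...) {
  deltas <- attr(object, "deltas")
  keep <- if (conserved_only) {
    paste(object$og_a, object$og_b, sep = "|")[object$conserved]
  } else deltas$pair
  long <- deltas %>%
    filter(.data$pair %in% keep) %>%
    tidyr::pivot_longer(-"pair", names_to = "comparison",
                        values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$comparison,
                                     fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", na.value = "grey80") +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5,
                                           hjust = 1, size = 6)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 ratio\ndifference")
}

#' Scores plot for a ratio-difference PCA
#'
#' @param object A `ratio_pca` object.
#' @param colour_by Optional named vector mapping comparison to a grouping
#'   label (e.g. species).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ratio_pca <- function(object, colour_by = NULL, ...) {
  d <- object$scores
  d$group <- if (is.null(colour_by)) "all" else colour_by[d$comparison]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$group,
                                  label = .data$comparison)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL)
}

#' Box summaries of per-TF promoter score differences
#'
#' @param tf_diff Output of [tf_difference_distribution()].
#' @param top_n Number of TFs to show, by absolute median difference.
#' @return A ggplot object.
#' @export
plot_tf_differences <- function(tf_diff, top_n = 20) {
  d <- head(tf_diff, top_n)
  d$tf <- factor(d$tf, levels = rev(d$tf))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median_diff, y = .data$tf)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = .data$q25,
                                        xmax = .data$q75), width = 0.3) +
    ggplot2::labs(x = "Median score difference (first - second)", y = NULL)
}
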