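#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_histogram
#'   geom_vline geom_col geom_line geom_tile labs scale_fill_gradient2
#'   theme_minimal
NULL

#' Plot measured versus cross-validated predicted survival
#'
#' @param object A `pls_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pls_cv
#' @export
autoplot.pls_cv <- function(object, ...) {
  df <- object$predictions
  p <- ggplot(df, aes(x = .data$measured, y = .data$predicted))
  if ("cell_line" %in% names(df)) p <- p + geom_point(aes(colour = .data$cell_line))
  else p <- p + geom_point()
  p + geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "Measured survival (% of control)",
         y = "Predicted survival (% of control)",
         title = sprintf("Leave-one-out predictions (R² = %.3f, %s)",
                         object$r2, object$r2_method)) +
    theme_minimal()
}

#' Plot the randomized-model null distribution
#'
#' @param object A `permutation_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot with the observed model R-squared marked.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, bins = 40, ...) {
  ggplot(tidy(object), aes(x = .data$r2)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$model_r2, colour = "red") +
    labs(x = expression(R^2~"of randomized models"), y = "Count",
         title = sprintf("z = %.2f, normal p = %.2g", object$z, object$p_value)) +
    theme_minimal()
}

#' Plot mean absolute coefficients per phosphoprotein
#'
#' @param object A `coef_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart in descending order of contribution.
#' @method autoplot coef_summary
#' @export
autoplot.coef_summary <- function(object, ...) {
  df <- object$per_protein
  df$protein <- factor(df$protein, levels = df$protein)
  ggplot(df, aes(x = .data$protein, y = .data$mean_abs_coef)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Mean |coefficient|",
         title = "Phosphoprotein contribution to the model") +
    theme_minimal()
}

#' Plot the incremental R-squared curve
#'
#' @param object An `incremental_curve`.
#' @param ... Unused.
#' @return A ggplot of R-squared as proteins are added in ranked order.
#' @method autoplot incremental_curve
#' @export
autoplot.incremental_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$step <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$step, y = .data$r2)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$protein) +
    labs(x = "Protein added (in coefficient-rank order)", y = expression(R^2)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of z-scored measurements with clustered ordering
#'
#' @param mat Numeric matrix (conditions x columns), typically already
#'   z-scored with [zscore_matrix()].
#' @param row_order,col_order Optional `cluster_ordering`s (or label
#'   vectors) fixing the axis orders.
#' @return A ggplot tile heatmap.
#' @export
plot_signal_heatmap <- function(mat, row_order = NULL, col_order = NULL) {
  mat <- as.matrix(mat)
  rl <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  cl <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  get_order <- function(o, fallback) {
    if (is.null(o)) return(fallback)
    if (inherits(o, "cluster_ordering")) o$leaf_order else o
  }
  rl_ord <- get_order(row_order, rl)
  cl_ord <- get_order(col_order, cl)
  df <- tibble::tibble(row = rep(rl, times = ncol(mat)),
                       col = rep(cl, each = nrow(mat)),
                       z = as.numeric(mat))
  df$row <- factor(df$row, levels = rev(rl_ord))
  df$col <- factor(df$col, levels = cl_ord)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
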