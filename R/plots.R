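#' Volcano plot of a differential-expression fit
#'
#' @param object a `deg_fit`.
#' @param alpha significance threshold for coloring.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot deg_fit
#' @export
autoplot.deg_fit <- function(object, alpha = 0.05, ...) {
  d <- tidy(object, alpha = alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC,
                                  y = -log10(.data$p_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = expression(-log[10]~p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Module size / cohesiveness overview plot
#'
#' @param object a `module_set`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$cohesiveness,
                               label = .data$module_id)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$density), alpha = 0.7) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "module size (genes)", y = "cohesiveness") +
    ggplot2::theme_minimal()
}

#' Heatmap of the clustered top DEGs
#'
#' Tiles the selected genes-by-samples submatrix with rows and columns in
#' dendrogram leaf order.
#'
#' @param object a `deg_cluster`.
#' @param expr the expression tibble it was built from.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot deg_cluster
#' @export
autoplot.deg_cluster <- function(object, expr, ...) {
  mat <- as_expr_matrix(expr)[object$genes, , drop = FALSE]
  d <- as_tibble(mat) |>
    mutate(gene_id = rownames(mat)) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "expression") |>
    mutate(gene_id = factor(.data$gene_id, levels = object$gene_order),
           sample_id = factor(.data$sample_id, levels = object$sample_order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                  fill = .data$expression)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b",
                                  midpoint = mean(d$expression)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
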