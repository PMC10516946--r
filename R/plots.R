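#' Plot a row-normalized confusion matrix as a heat table
#'
#' Rows are ground-truth grades, columns predictions; cell shading follows
#' the row-normalized fraction and each cell is annotated with the count.
#' Requires ggplot2.
#'
#' @param cm a confusion matrix (e.g. `metrics_report$confusion`).
#' @return a ggplot object.
#' @export
plot_confusion <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_confusion requires ggplot2")
  rn <- row_normalize(cm)
  df <- data.frame(true = factor(rep(rownames(cm), ncol(cm)),
                                 levels = rev(rownames(cm))),
                   pred = factor(rep(colnames(cm), each = nrow(cm)),
                                 levels = colnames(cm)),
                   frac = as.vector(rn), count = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = pred, y = true,
                                   fill = frac)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.2f)", count, frac)),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1), name = "row fraction") +
    ggplot2::labs(x = "predicted severity", y = "ground truth severity") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param roc output of [roc_auc_ovr()] (or `metrics_report$roc`).
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_roc requires ggplot2")
  df <- roc$curves
  df$class <- factor(df$class,
                     labels = sprintf("grade %d (AUC %.2f)",
                                      sort(unique(df$class)),
                                      roc$auc[sort(unique(df$class)) + 1L]))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr,
                                   color = class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         color = "grey50") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}
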