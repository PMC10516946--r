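#' Stratified five-fold train/validation/test split
#'
#' The five test sets form a stratified partition of the dataset (each
#' record is tested exactly once); within each fold the remaining records
#' are split 7:1 into training and validation, also stratified, so the
#' overall proportions are approximately 70% training, 10% validation and
#' 20% testing.
#'
#' @param labels integer class labels (0-based grades).
#' @param seed integer seed; the assignment is deterministic given it.
#' @param n_folds number of folds (default 5).
#' @return an object of class `fold_assignment`: list with `folds` (one
#'   `list(train, val, test)` of index vectors per fold), `test_fold`
#'   (per-record test-fold id) and `seed`.
#' @export
split_dataset <- function(labels, seed = 1L, n_folds = 5L) {
  labels <- as.integer(labels)
  n <- length(labels)
  tab <- table(labels)
  low <- names(tab)[tab < n_folds]
  if (length(low))
    stop("class(es) with fewer than ", n_folds, " members: ",
         paste(low, collapse = ", "))
  with_seed(as.integer(seed), function() {
    # deal shuffled members of each class into folds with one continuous
    # cycle across classes: per-class counts stay within 1 of n_c/n_folds
    # (stratification) and fold totals are exactly balanced when n is a
    # multiple of n_folds (e.g. 190 records -> five test folds of 38)
    test_fold <- integer(n)
    ordered <- unlist(lapply(sort(unique(labels)), function(cl)
      sample(which(labels == cl))))
    test_fold[ordered] <- rep_len(seq_len(n_folds), n)
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- which(test_fold == f)
      rest <- which(test_fold != f)
      val <- integer(0)
      for (cl in unique(labels)) {
        pool <- sample(rest[labels[rest] == cl])
        nv <- max(1L, round(length(pool) / 8))   # 7:1 train:val
        val <- c(val, pool[seq_len(nv)])
      }
      list(train = sort(setdiff(rest, val)), val = sort(val),
           test = sort(test))
    })
    structure(list(folds = folds, test_fold = test_fold,
                   seed = as.integer(seed)),
              class = "fold_assignment")
  })
}

#' Confusion matrix of severity predictions
#'
#' @param y_true,y_pred integer grade vectors (0-based, same length).
#' @param n_classes number of grades (default 4).
#' @return `n_classes x n_classes` integer matrix; rows are ground truth,
#'   columns the predictions.
#' @export
confusion <- function(y_true, y_pred, n_classes = 4L) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes))
    stop("labels must be in 0..", n_classes - 1L)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is TP over the column sum, recall TP over the row sum, F1
#' their harmonic mean. A class never predicted (empty column) or absent
#' (empty row) gets metric 0 with a warning.
#'
#' @param cm confusion matrix (rows truth, columns prediction).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_metrics <- function(cm) {
  tp <- diag(cm)
  col <- colSums(cm)
  row <- rowSums(cm)
  if (any(col == 0) || any(row == 0))
    warning("empty row/column in confusion matrix; affected metrics set to 0")
  precision <- ifelse(col > 0, tp / col, 0)
  recall <- ifelse(row > 0, tp / row, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = 0:(nrow(cm) - 1L), precision = precision,
             recall = recall, f1 = f1, support = as.integer(row),
             row.names = NULL)
}

#' Support-weighted totals of per-class metrics
#'
#' Aggregates per-class metrics as `sum(metric * support) / sum(support)` —
#' the convention under which the per-class rows of a classification report
#' reproduce its printed totals. Accuracy is `trace(cm) / n` when the
#' confusion matrix is given.
#'
#' @param metrics data.frame from [per_class_metrics()] (columns
#'   `precision`, `recall`, `f1`, `support`), or a numeric vector of one
#'   metric.
#' @param supports per-class supports (taken from `metrics$support` if
#'   missing).
#' @param cm optional confusion matrix for the accuracy.
#' @return named list: `precision`, `recall`, `f1` (or `total` for a
#'   vector input), plus `accuracy` when `cm` is supplied.
#' @export
weighted_totals <- function(metrics, supports = NULL, cm = NULL) {
  if (is.numeric(metrics) && is.null(dim(metrics))) {
    if (is.null(supports)) stop("supports required with a metric vector")
    if (sum(supports) == 0) stop("zero total support")
    return(list(total = sum(metrics * supports) / sum(supports)))
  }
  if (is.null(supports)) supports <- metrics$support
  if (sum(supports) == 0) stop("zero total support")
  out <- list(
    precision = sum(metrics$precision * supports) / sum(supports),
    recall = sum(metrics$recall * supports) / sum(supports),
    f1 = sum(metrics$f1 * supports) / sum(supports))
  if (!is.null(cm)) out$accuracy <- sum(diag(cm)) / sum(cm)
  out
}

#' One-vs-rest ROC curves and AUC per class
#'
#' AUC is computed with the rank (Mann-Whitney) statistic using midranks
#' for ties; ROC points are exported for plotting.
#'
#' @param y_true integer grades (0-based).
#' @param probs `n x n_classes` matrix of predicted class probabilities
#'   (rows sum to 1).
#' @param n_classes number of grades.
#' @return list with `auc` (per-class, `NA` and a flag for classes absent
#'   from `y_true`), `curves` (data.frame `class`, `fpr`, `tpr`) and
#'   `flagged` (classes with undefined AUC).
#' @export
roc_auc_ovr <- function(y_true, probs, n_classes = 4L) {
  y_true <- as.integer(y_true)
  probs <- as.matrix(probs)
  if (nrow(probs) != length(y_true))
    stop("probs must have one row per label")
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    warning("probability rows do not sum to 1")
  auc <- rep(NA_real_, n_classes)
  curves <- NULL
  flagged <- integer(0)
  for (cl in 0:(n_classes - 1L)) {
    pos <- y_true == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      flagged <- c(flagged, cl)
      next
    }
    s <- probs[, cl + 1L]
    r <- rank(s)                                   # midranks for ties
    auc[cl + 1L] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(s, decreasing = TRUE)
    tpr <- cumsum(pos[ord]) / n1
    fpr <- cumsum(!pos[ord]) / n0
    curves <- rbind(curves,
                    data.frame(class = cl, fpr = c(0, fpr), tpr = c(0, tpr)))
  }
  list(auc = auc, curves = curves, flagged = flagged)
}

#' Row-normalize a confusion matrix
#'
#' Each row is divided by its sum, so the diagonal equals the per-class
#' recall (sensitivity) — the form in which confusion matrices of severity
#' indices are usually displayed.
#'
#' @param cm confusion matrix.
#' @return matrix of row fractions (all-zero rows stay zero).
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(cm, 1L, ifelse(rs > 0, rs, 1), "/")
  out
}

#' Agreement within k severity grades
#'
#' Fraction of predictions whose grade differs from the ground truth by at
#' most `k` — the band of width `2k + 1` around the confusion-matrix
#' diagonal. `k = 0` reduces to per-class recall / overall accuracy; for a
#' 4-grade index `k = 3` is always 1.
#'
#' @param cm confusion matrix.
#' @param k maximum allowed grade difference (default 1).
#' @return list with `per_class` (per true grade) and `overall`.
#' @export
within_k_agreement <- function(cm, k = 1L) {
  if (k < 0L) stop("k must be >= 0")
  nc <- nrow(cm)
  band <- abs(outer(seq_len(nc), seq_len(nc), "-")) <= k
  rs <- rowSums(cm)
  per_class <- ifelse(rs > 0, rowSums(cm * band) / rs, NA_real_)
  names(per_class) <- rownames(cm)
  list(per_class = per_class, overall = sum(cm * band) / sum(cm))
}

#' Cross-validated evaluation of the severity classifier
#'
#' Trains one model per fold on that fold's training split (early-stopping
#' on its validation split), predicts the held-out test split, and pools
#' everything the evaluation protocol reports: the pooled confusion matrix,
#' per-class precision/recall/F1 (mean and SD across folds), one-vs-rest
#' AUC on the pooled predictions, support-weighted totals, accuracy and
#' within-one-grade agreement.
#'
#' @param data rendered dataset from [render_dataset()].
#' @param assignment a `fold_assignment` from [split_dataset()].
#' @param config an [mvcnn_config()].
#' @return an object of class `metrics_report`.
#' @export
cross_validate <- function(data, assignment, config = mvcnn_config()) {
  n <- length(data$x)
  labels <- as.integer(data$labels)
  y_pred <- integer(n)
  probs <- matrix(NA_real_, n, config$n_classes)
  fold_metrics <- list()
  for (f in seq_along(assignment$folds)) {
    fd <- assignment$folds[[f]]
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_mvcnn(data, cfg, train_idx = fd$train, val_idx = fd$val)
    pt <- predict_prob_matrix(model, data$x[fd$test])
    probs[fd$test, ] <- pt
    y_pred[fd$test] <- max.col(pt) - 1L
    cmf <- confusion(labels[fd$test], y_pred[fd$test], config$n_classes)
    pcf <- per_class_metrics(cmf)
    pcf$fold <- f
    fold_metrics[[f]] <- pcf
  }
  cm <- confusion(labels, y_pred, config$n_classes)
  per_class <- per_class_metrics(cm)
  folds_df <- do.call(rbind, fold_metrics)
  sd_by_class <- function(col)
    vapply(0:(config$n_classes - 1L), function(cl)
      stats::sd(folds_df[[col]][folds_df$class == cl]), 1)
  per_class$precision_sd <- sd_by_class("precision")
  per_class$recall_sd <- sd_by_class("recall")
  per_class$f1_sd <- sd_by_class("f1")
  roc <- roc_auc_ovr(labels, probs, config$n_classes)
  per_class$auc <- roc$auc
  totals <- weighted_totals(per_class, cm = cm)
  totals$auc <- sum(roc$auc * per_class$support, na.rm = TRUE) /
    sum(per_class$support[!is.na(roc$auc)])
  structure(list(per_class = per_class, totals = totals,
                 confusion = cm, row_normalized = row_normalize(cm),
                 within_1 = within_k_agreement(cm, 1L),
                 roc = roc, fold_metrics = folds_df,
                 y_pred = y_pred, probs = probs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  class %d (n=%d): P %.3f  R %.3f  F1 %.3f  AUC %s\n",
                pc$class[i], pc$support[i], pc$precision[i], pc$recall[i],
                pc$f1[i],
                ifelse(is.na(pc$auc[i]), "NA", sprintf("%.3f", pc$auc[i]))))
  cat(sprintf("  total (n=%d): P %.3f  R %.3f  F1 %.3f  acc %.3f\n",
              sum(pc$support), x$totals$precision, x$totals$recall,
              x$totals$f1, x$totals$accuracy))
  cat(sprintf("  within-1-grade agreement: %.3f\n", x$within_1$overall))
  invisible(x)
}

#' Write a metrics report as JSON and CSV
#'
#' @param report a `metrics_report`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_per_class.csv`.
#' @return the two paths, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  js <- paste0(prefix, ".json")
  cs <- paste0(prefix, "_per_class.csv")
  jsonlite::write_json(list(per_class = report$per_class,
                            totals = report$totals,
                            confusion = report$confusion,
                            within_1 = report$within_1),
                       js, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_class, cs, row.names = FALSE)
  invisible(c(js, cs))
}
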