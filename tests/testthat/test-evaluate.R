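test_that("stratified five-fold split partitions test sets at 70/10/20", {
  labels <- rep(0:3, c(62, 45, 45, 38))
  fa <- split_dataset(labels, seed = 4)
  tests <- lapply(fa$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_along(labels))  # partition
  expect_equal(vapply(tests, length, 1L), rep(38L, 5))  # folds of 38
  for (fd in fa$folds) {
    expect_length(intersect(fd$train, fd$val), 0L)
    expect_length(intersect(fd$train, fd$test), 0L)
    expect_length(intersect(fd$val, fd$test), 0L)
    expect_setequal(c(fd$train, fd$val, fd$test), seq_along(labels))
    expect_lt(abs(length(fd$val) / (length(fd$train) + length(fd$val)) -
                    1 / 8), 0.015)
    # stratification: every class in every role
    for (cl in 0:3)
      for (role in fd) expect_gt(sum(labels[role] == cl), 0L)
  }
  fa2 <- split_dataset(labels, seed = 4)
  expect_identical(fa, fa2)
  expect_error(split_dataset(c(0, 0, 0, 1, 1, 1, 2, 3), seed = 1), "fewer")
})

test_that("confusion counts match hand enumeration and conserve totals", {
  cm <- confusion(c(0, 0, 1), c(0, 1, 1))
  expect_equal(cm[1, ], c(1, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(cm[2, ], c(0, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(sum(cm), 3)
  y <- sample(0:3, 100, replace = TRUE)
  expect_equal(confusion(y, y), diag(table(factor(y, 0:3))),
               ignore_attr = TRUE)
  expect_error(confusion(c(0, 4), c(0, 0)), "labels")
  expect_error(confusion(0:1, 0L), "length")
})

test_that("per-class metrics reproduce published precision/recall arithmetic", {
  # F1 identities from printed per-class precision and recall
  f1 <- function(p, r) 2 * p * r / (p + r)
  # printed-precision agreement: the published table rounds F1 computed
  # from unrounded precision/recall, so match to +-0.001, not digit-exact
  expect_equal(f1(0.914, 0.855), 0.883, tolerance = 1e-3)
  expect_equal(f1(0.882, 0.789), 0.833, tolerance = 1e-3)
  # identity confusion matrix: all metrics 1
  pc <- per_class_metrics(diag(c(5L, 6L, 7L, 8L)))
  expect_equal(pc$precision, rep(1, 4))
  expect_equal(pc$recall, rep(1, 4))
  expect_equal(pc$f1, rep(1, 4))
  expect_equal(pc$support, c(5L, 6L, 7L, 8L))
  # degenerate empty column -> 0 with a warning
  cm <- matrix(c(2L, 0L, 0L, 0L,
                 2L, 0L, 0L, 0L,
                 0L, 0L, 3L, 0L,
                 0L, 0L, 0L, 3L), 4, byrow = TRUE)
  expect_warning(pcd <- per_class_metrics(cm), "empty")
  expect_equal(pcd$precision[2], 0)
  expect_equal(pcd$f1[2], 0)
})

test_that("support-weighted totals match the published report conventions", {
  supports <- c(62, 45, 45, 38)
  expect_equal(round(weighted_totals(c(0.914, 0.739, 0.731, 0.882),
                                     supports)$total, 3), 0.823)
  expect_equal(round(weighted_totals(c(0.855, 0.756, 0.844, 0.789),
                                     supports)$total, 3), 0.816)
  # equal supports reduce to the arithmetic mean
  expect_equal(weighted_totals(c(0.2, 0.4, 0.6, 0.8), rep(10, 4))$total, 0.5)
  # a single nonzero support picks out that class
  expect_equal(weighted_totals(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 9, 0))$total,
               0.6)
  expect_error(weighted_totals(rep(0.5, 4), rep(0, 4)), "support")
})

test_that("one-vs-rest AUC equals the pair-counting oracle, with midrank ties", {
  # perfectly separating scores
  y <- c(0, 0, 0, 1, 1, 2, 3, 3)
  probs <- matrix(0.05, 8, 4)
  probs[cbind(seq_along(y), y + 1)] <- 0.85
  roc <- roc_auc_ovr(y, probs / rowSums(probs))
  expect_equal(roc$auc, rep(1, 4))
  # label-independent scores approach chance
  set.seed(40)
  n <- 4000
  yl <- sample(0:3, n, replace = TRUE)
  pr <- matrix(runif(n * 4), n)
  pr <- pr / rowSums(pr)
  expect_equal(roc_auc_ovr(yl, pr)$auc, rep(0.5, 4), tolerance = 0.05)
  # 6-point toy sets against brute-force concordance counting (with ties)
  for (seed in 1:10) {
    set.seed(seed)
    y6 <- c(0, 0, 0, 1, 1, 1)
    s <- sample(seq(0.1, 0.9, 0.2), 6, replace = TRUE)
    p6 <- cbind(s, 1 - s, 0, 0)
    p6 <- p6 / rowSums(p6)
    roc6 <- roc_auc_ovr(y6, p6)
    expect_equal(roc6$auc[1], auc_pair_count(p6[, 1], y6 == 0))
    expect_true(all(c(2, 3) %in% roc6$flagged))
  }
})

test_that("row normalization puts per-class recall on the diagonal", {
  cm <- confusion(c(0, 0, 1), c(0, 1, 1))
  rn <- row_normalize(cm)
  expect_equal(rn[1, ], c(0.5, 0.5, 0, 0), ignore_attr = TRUE)
  expect_equal(rn[2, ], c(0, 1, 0, 0), ignore_attr = TRUE)
  set.seed(50)
  for (i in 1:25) {
    m <- matrix(rpois(16, 4), 4)
    m[1, ] <- m[1, ] + 1     # keep rows non-empty
    rec <- suppressWarnings(per_class_metrics(m)$recall)
    expect_equal(unname(diag(row_normalize(m))), rec, tolerance = 1e-12)
    expect_equal(unname(rowSums(row_normalize(m))), rep(1, 4))
  }
  # uniform row
  expect_equal(unname(row_normalize(matrix(1L, 4, 4))[1, ]), rep(0.25, 4))
})

test_that("within-k agreement is the banded fraction, monotone in k", {
  cm <- matrix(c(5L, 1L, 0L, 0L,
                 1L, 6L, 1L, 0L,
                 0L, 2L, 7L, 1L,
                 0L, 0L, 1L, 5L), 4, byrow = TRUE)
  w0 <- within_k_agreement(cm, 0)
  expect_equal(w0$overall, sum(diag(cm)) / sum(cm))
  expect_equal(unname(w0$per_class),
               suppressWarnings(per_class_metrics(cm)$recall))
  expect_equal(within_k_agreement(cm, 1)$overall, 1)  # band-only matrix
  # a prediction two grades off has zero within-1 credit for its class
  cm2 <- diag(4L)
  cm2[1, ] <- c(0L, 0L, 1L, 0L)
  expect_equal(unname(within_k_agreement(cm2, 1)$per_class[1]), 0)
  set.seed(60)
  m <- matrix(rpois(16, 3), 4)
  vals <- vapply(0:3, function(k) within_k_agreement(m, k)$overall, 1)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[4], 1)
})

test_that("AUC midrank statistic agrees with an established ROC package", {
  skip_if_not_installed("pROC")
  set.seed(70)
  y <- sample(0:3, 60, replace = TRUE)
  pr <- matrix(runif(240), 60)
  pr <- pr / rowSums(pr)
  ours <- roc_auc_ovr(y, pr)$auc
  for (cl in 0:3) {
    ref <- suppressMessages(pROC::auc(as.integer(y == cl), pr[, cl + 1],
                                      direction = "<"))
    expect_equal(ours[cl + 1], as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("cross-validation on a small rendered set emits a coherent report", {
  man <- generate_dataset(6L, withr::local_tempdir(), seed = 91)
  data <- render_dataset(man, icosphere_cameras(0, 3), 32)
  fa <- split_dataset(data$labels, seed = 2)
  cfg <- mvcnn_config(resolution = 32L, conv_channels = c(4L, 8L),
                      final_channels = 8L, epochs = 3L, batch_size = 6L,
                      seed = 5)
  # 3-epoch models on 24 shapes leave some classes unpredicted: the
  # empty-column warning is expected here
  rep <- suppressWarnings(cross_validate(data, fa, cfg))
  expect_s3_class(rep, "metrics_report")
  expect_equal(sum(rep$confusion), nrow(man))
  expect_equal(rep$per_class$support, as.vector(table(data$labels)))
  with(rep$per_class, {
    expect_true(all(precision >= 0 & precision <= 1))
    expect_true(all(recall >= 0 & recall <= 1))
    expect_true(all(f1 >= 0 & f1 <= 1))
    expect_true(all(is.na(auc) | (auc >= 0 & auc <= 1)))
  })
  # five fold-wise entries per class and metric
  expect_equal(nrow(rep$fold_metrics), 20L)
  expect_equal(unname(diag(rep$row_normalized)), rep$per_class$recall)
  expect_gte(rep$within_1$overall, rep$totals$accuracy)
  f <- withr::local_tempfile()
  write_metrics_report(rep, f)
  expect_true(file.exists(paste0(f, ".json")))
})
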