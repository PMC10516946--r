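#' Configuration of the multi-view severity classifier
#'
#' The classifier encodes every rendered view with a small convolutional
#' stack (3x3 kernels, strides per `conv_strides`, a final stride-1 block,
#' ReLU after every block), global-average
#' pools the final feature maps into one vector per view (the projection is
#' the identity: pooled dimension equals `final_channels`), aggregates the
#' views with a gated attention layer, and maps the aggregate to 4 severity
#' logits.
#'
#' @param resolution render resolution the model expects (pixels).
#' @param in_channels input image channels (3 normals + depth).
#' @param conv_channels output channels of the intermediate conv blocks.
#' @param conv_strides stride of each intermediate conv block (same length
#'   as `conv_channels`; the final block always has stride 1). The default
#'   `c(2, 2, 1)` keeps the final feature maps at a quarter of the render
#'   resolution; they bound the spatial resolution of the class activation
#'   maps.
#' @param final_channels channels K of the final (stride-1) conv block whose
#'   post-ReLU maps are the Grad-CAM feature maps.
#' @param attn_hidden hidden width of the gated attention scorer.
#' @param n_classes number of severity grades.
#' @param epochs,batch_size,lr,weight_decay,patience training-loop
#'   hyperparameters
#'   (Adam with decoupled weight decay; `patience` = early-stopping epochs
#'   without validation improvement).
#' @param class_weights use inverse-frequency class weights in the loss
#'   (the default: clinical severity cohorts are imbalanced).
#' @param erase_prob random-erasing augmentation: probability that a
#'   training view has a random rectangle (20-50% of the frame side)
#'   replaced by background, discouraging whole-silhouette shortcuts.
#'   Off by default: it slows convergence when thin structures (a narrow
#'   palatal bridge) carry class evidence.
#' @param seed RNG seed for weight init and batch shuffling.
#' @return a list of class `mvcnn_config`.
#' @export
mvcnn_config <- function(resolution = 64L, in_channels = 4L,
                         conv_channels = c(8L, 16L, 32L),
                         conv_strides = NULL,
                         final_channels = 32L, attn_hidden = 16L,
                         n_classes = 4L, epochs = 90L, batch_size = 8L,
                         lr = 2e-3, weight_decay = 0, patience = 15L,
                         class_weights = TRUE, erase_prob = 0,
                         seed = 42L) {
  if (is.null(conv_strides))
    conv_strides <- if (length(conv_channels) == 3L) c(2L, 2L, 1L)
                    else rep(2L, length(conv_channels))
  stopifnot(resolution >= 16L, epochs >= 0L, batch_size >= 1L, lr > 0,
            patience >= 1L, n_classes >= 2L,
            length(conv_strides) == length(conv_channels))
  sz <- resolution
  for (s in conv_strides) {
    if (sz %% s != 0L) stop("resolution not divisible by the conv strides")
    sz <- sz %/% s
  }
  structure(list(resolution = as.integer(resolution),
                 in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 conv_strides = as.integer(conv_strides),
                 final_channels = as.integer(final_channels),
                 attn_hidden = as.integer(attn_hidden),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 patience = as.integer(patience),
                 class_weights = isTRUE(class_weights),
                 erase_prob = erase_prob,
                 seed = as.integer(seed)),
            class = "mvcnn_config")
}

#' Initialize an untrained multi-view classifier
#'
#' He-initialized conv kernels, small random attention/classifier weights,
#' all biases zero (so an all-zero image produces all-zero feature maps and
#' the conv stack is positively homogeneous at initialization).
#'
#' @param config an [mvcnn_config()].
#' @return an object of class `mvcnn`.
#' @export
mvcnn_init <- function(config = mvcnn_config()) {
  geo <- conv_stack_geometry(config)
  with_seed(config$seed, function() {
    w <- list()
    for (l in seq_along(geo$strides)) {
      cin <- geo$channels[l]
      cout <- geo$channels[l + 1L]
      w[[paste0("conv", l, "_W")]] <-
        matrix(stats::rnorm(cout * 9L * cin, sd = sqrt(2 / (9 * cin))),
               cout, 9L * cin)
      w[[paste0("conv", l, "_b")]] <- numeric(cout)
    }
    D <- config$final_channels
    h <- config$attn_hidden
    w$attn_V <- matrix(stats::rnorm(h * D, sd = sqrt(1 / D)), h, D)
    w$attn_bV <- numeric(h)
    w$attn_U <- matrix(stats::rnorm(h * D, sd = sqrt(1 / D)), h, D)
    w$attn_bU <- numeric(h)
    w$attn_w <- stats::rnorm(h, sd = sqrt(1 / h))
    w$cls_W <- matrix(stats::rnorm(config$n_classes * D, sd = sqrt(1 / D)),
                      config$n_classes, D)
    w$cls_b <- numeric(config$n_classes)
    structure(list(weights = w, config = config, log = NULL,
                   class_weights = rep(1, config$n_classes)),
              class = "mvcnn")
  })
}

#' @export
print.mvcnn <- function(x, ...) {
  npar <- sum(vapply(x$weights, length, 1L))
  cat(sprintf("mvcnn: %d parameters, %dpx input, %d classes%s\n",
              npar, x$config$resolution, x$config$n_classes,
              if (is.null(x$log)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$log))))
  invisible(x)
}

# (H, W, C[, V]) image tensor -> channel-first (C, S*V) matrix.
flatten_views <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x <- aperm(x, c(3L, 1L, 2L, 4L))
  dim(x) <- c(dim(x)[1L], prod(dim(x)[-1L]))
  x
}

#' Encode one rendered view
#'
#' Runs the per-view conv stack on a single image and returns the post-ReLU
#' final conv maps (the Grad-CAM feature maps A^k) and the pooled feature
#' vector (their spatial global average).
#'
#' @param model an `mvcnn`.
#' @param image `(H, W, C)` array matching the configured resolution and
#'   channel count (e.g. `rendered_view$channels`).
#' @return list with `conv_maps` (`h x w x K` array) and `pooled` (length-K
#'   vector).
#' @export
encode_view <- function(model, image) {
  d <- dim(image)
  cfg <- model$config
  if (length(d) != 3L || d[1L] != cfg$resolution || d[2L] != cfg$resolution ||
      d[3L] != cfg$in_channels)
    stop(sprintf("image must be %d x %d x %d", cfg$resolution,
                 cfg$resolution, cfg$in_channels))
  enc <- conv_stack_forward(model$weights, cfg, flatten_views(image))
  So <- dim(enc$A)[1L]
  side <- as.integer(sqrt(So))
  maps <- enc$A[, , 1L]
  dim(maps) <- c(side, side, cfg$final_channels)
  list(conv_maps = maps, pooled = as.vector(enc$pooled))
}

#' Aggregate per-view features with the gated attention layer
#'
#' Scores every view with the learned gated scorer, softmax-normalizes the
#' scores into convex weights (non-negative, summing to 1), and returns the
#' attention-weighted sum of the pooled vectors. Permutation of the views
#' permutes the weights and leaves the aggregate unchanged.
#'
#' @param model an `mvcnn`.
#' @param pooled a `D x V` matrix of pooled view features (or a list of
#'   length-D vectors).
#' @return list with `weights` (length V) and `aggregated` (length D).
#' @export
attention_aggregate <- function(model, pooled) {
  if (is.list(pooled)) pooled <- do.call(cbind, pooled)
  pooled <- as.matrix(pooled)
  if (ncol(pooled) < 1L) stop("need at least one view")
  P <- pooled
  dim(P) <- c(nrow(pooled), ncol(pooled), 1L)
  at <- attn_forward(model$weights, P)
  list(weights = as.vector(at$a), aggregated = as.vector(at$z))
}

#' Classify an aggregated shape descriptor
#'
#' @param model an `mvcnn`.
#' @param aggregated length-D aggregated feature vector.
#' @return list with `logits` and `probs` (both length `n_classes`; probs
#'   are the softmax of the logits).
#' @export
classify <- function(model, aggregated) {
  logits <- as.vector(model$weights$cls_W %*% aggregated +
                      model$weights$cls_b)
  e <- exp(logits - max(logits))
  list(logits = logits, probs = e / sum(e))
}

#' Predict the severity grade of a mesh
#'
#' Composes the full pipeline: pose normalization, fly-by rendering from
#' the view set, per-view encoding, attention aggregation and the softmax
#' severity head. Deterministic given the model weights.
#'
#' @param object a trained `mvcnn`.
#' @param mesh a [triangle_mesh] (pose is normalized internally).
#' @param viewset a `view_set`; default 12 cameras at radius 3.
#' @param ... unused.
#' @return list with `class` (predicted grade 0-3), `probs`, `logits`,
#'   `attention` (per-view weights).
#' @export
predict.mvcnn <- function(object, mesh, viewset = icosphere_cameras(), ...) {
  views <- render_all(normalize_pose(mesh), viewset,
                      resolution = object$config$resolution)
  out <- predict_rendered(object, views_to_tensor(views))
  out
}

#' Predict from an already-rendered view tensor
#'
#' @param model a trained `mvcnn`.
#' @param x `(H, W, C, V)` array of stacked view images (see
#'   [render_dataset()]).
#' @return as [predict.mvcnn()].
#' @export
predict_rendered <- function(model, x) {
  fw <- mvcnn_forward(model$weights, model$config, flatten_views(x),
                      V = dim(x)[4L], B = 1L)
  list(class = which.max(fw$probs[, 1L]) - 1L,
       probs = as.vector(fw$probs),
       logits = as.vector(fw$logits),
       attention = as.vector(fw$attn))
}

# Forward a list of view tensors in mini-batches; returns n x 4 prob matrix.
predict_prob_matrix <- function(model, xlist, batch = 16L) {
  n <- length(xlist)
  out <- matrix(0, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    idx <- i:min(n, i + batch - 1L)
    X <- stack_batch(xlist[idx])
    fw <- mvcnn_forward(model$weights, model$config, X$X, X$V, length(idx))
    out[idx, ] <- t(fw$probs)
    i <- i + batch
  }
  out
}

stack_batch <- function(xlist) {
  d <- dim(xlist[[1L]])
  V <- d[4L]
  S <- d[1L] * d[2L]
  X <- matrix(0, d[3L], S * V * length(xlist))
  for (b in seq_along(xlist))
    X[, (b - 1L) * S * V + seq_len(S * V)] <- flatten_views(xlist[[b]])
  list(X = X, V = V)
}

#' Train the multi-view severity classifier
#'
#' Minimizes (optionally class-weighted) cross-entropy with Adam over
#' mini-batches of meshes, early-stopping on validation loss. Rendering is
#' done up front ([render_dataset()]); the training loop only touches image
#' tensors. Reproducible for a fixed `config$seed`.
#'
#' @param data a rendered dataset: list with `x` (list of `(H, W, C, V)`
#'   arrays) and `labels` (integer grades 0-3), as from [render_dataset()].
#' @param config an [mvcnn_config()].
#' @param train_idx,val_idx integer indices into `data$x`. `train_idx`
#'   defaults to all records; without `val_idx` no early stopping is done.
#' @return a trained `mvcnn`; `$log` holds per-epoch training loss,
#'   validation loss and validation accuracy.
#' @export
train_mvcnn <- function(data, config = mvcnn_config(), train_idx = NULL,
                        val_idx = NULL) {
  n <- length(data$x)
  if (is.null(train_idx)) train_idx <- seq_len(n)
  labels <- as.integer(data$labels)
  nc <- config$n_classes
  counts <- tabulate(labels[train_idx] + 1L, nc)
  if (any(counts == 0L))
    warning("class(es) absent from training split: ",
            paste(which(counts == 0L) - 1L, collapse = ", "),
            "; their loss weight is 0")
  wclass <- rep(1, nc)
  if (config$class_weights) {
    present <- counts > 0L
    wclass[present] <- sum(counts) / (sum(present) * counts[present])
    wclass[!present] <- 0
  }
  model <- mvcnn_init(config)
  model$class_weights <- wclass
  if (config$epochs == 0L) return(model)
  w <- model$weights
  opt <- adam_init(w)
  V <- dim(data$x[[1L]])[4L]
  log <- NULL
  best <- list(loss = Inf, weights = w, epoch = 0L)
  wait <- 0L
  with_seed(config$seed + 1L, function() {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_loss <- 0
      for (bidx in splits) {
        B <- length(bidx)
        X <- stack_batch(data$x[bidx])
        if ((config$erase_prob %||% 0) > 0)
          X$X <- erase_views(X$X, config$resolution, config$erase_prob)
        fw <- mvcnn_forward(w, config, X$X, V, B)
        y <- labels[bidx]
        pick <- cbind(y + 1L, seq_len(B))
        wy <- wclass[y + 1L]
        tr_loss <- tr_loss - sum(wy * log(pmax(fw$probs[pick], 1e-12)))
        dlogits <- sweep(fw$probs, 2L, wy, "*")
        dlogits[pick] <- dlogits[pick] - wy
        dlogits <- dlogits / B
        grads <- mvcnn_backward(w, config, fw, dlogits)
        upd <- adam_step(w, grads, opt, lr = config$lr,
                         weight_decay = config$weight_decay %||% 0)
        w <<- upd$weights
        opt <<- upd$state
      }
      tr_loss <- tr_loss / length(ord)
      val_loss <- NA_real_
      val_acc <- NA_real_
      if (length(val_idx)) {
        model$weights <- w
        pv <- predict_prob_matrix(model, data$x[val_idx])
        yv <- labels[val_idx]
        val_loss <- -mean(wclass[yv + 1L] *
                          log(pmax(pv[cbind(seq_along(yv), yv + 1L)], 1e-12)))
        val_acc <- mean(max.col(pv) - 1L == yv)
      }
      log <<- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                    val_loss = val_loss, val_acc = val_acc))
      if (length(val_idx)) {
        if (val_loss < best$loss - 1e-6) {
          best <<- list(loss = val_loss, weights = w, epoch = epoch)
          wait <<- 0L
        } else {
          wait <<- wait + 1L
          if (wait >= config$patience) break
        }
      }
    }
  })
  model$weights <- if (length(val_idx) && is.finite(best$loss))
    best$weights else w
  model$log <- log
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the weights, the full config
#' (including the seed) and the training log.
#'
#' @param model a `mvcnn`.
#' @param path checkpoint file path.
#' @return `path` invisibly; `load_checkpoint` returns the `mvcnn`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "mvcnn")
}
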