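# Internal convolutional-network machinery for the multi-view classifier.
#
# There is no deep-learning framework in the package's dependency set, and
# the network is deliberately small, so the forward and backward passes are
# written directly on BLAS matrix products (im2col convolutions). The
# backward pass is validated against a finite-difference oracle in the test
# suite. Activation tensors are stored as (spatial, channels, images)
# arrays with column-major spatial flattening (row index fastest).

# Precompute the im2col gather indices for one conv layer geometry:
# P0[q, s] is the 1-based unpadded spatial source index of kernel tap q at
# output position s, or 0 where the tap falls in the zero padding.
make_conv_plan <- function(H, W, kernel = 3L, stride = 1L, pad = 1L) {
  Ho <- (H + 2L * pad - kernel) %/% stride + 1L
  Wo <- (W + 2L * pad - kernel) %/% stride + 1L
  io <- rep(seq_len(Ho), times = Wo)         # output rows, fastest
  jo <- rep(seq_len(Wo), each = Ho)
  di <- rep(0:(kernel - 1L), times = kernel) # within-patch offsets
  dj <- rep(0:(kernel - 1L), each = kernel)
  P0 <- matrix(0L, kernel^2, Ho * Wo)
  for (q in seq_len(kernel^2)) {
    ii <- (io - 1L) * stride + di[q] + 1L - pad   # unpadded source coords
    jj <- (jo - 1L) * stride + dj[q] + 1L - pad
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    P0[q, ok] <- (jj[ok] - 1L) * H + ii[ok]
  }
  list(H = H, W = W, Ho = Ho, Wo = Wo, S = H * W, So = Ho * Wo,
       k2 = kernel^2, P0 = P0, stride = stride)
}

plan_cache <- new.env(parent = emptyenv())

conv_plan_cached <- function(H, W, stride) {
  key <- paste(H, W, stride, sep = "_")
  if (is.null(plan_cache[[key]]))
    plan_cache[[key]] <- make_conv_plan(H, W, kernel = 3L, stride = stride,
                                        pad = 1L)
  plan_cache[[key]]
}

# Activations live channel-first: a (K, S*N) matrix for K channels,
# S spatial positions and N images, so every conv is a single GEMM.
conv_forward <- function(Wm, b, X, C, N, plan) {
  patches <- .im2col_cpp(X, plan$P0, C, plan$S, N)
  pre <- Wm %*% patches
  pre <- pre + b                                   # recycles down columns
  list(pre = pre, patches = patches, C = C, N = N)
}

# dPre: (Kout, So*N) gradient at the pre-activations.
conv_backward <- function(Wm, dPre, cache, plan) {
  dW <- tcrossprod(dPre, cache$patches)
  db <- rowSums(dPre)
  dPatch <- crossprod(Wm, dPre)                    # (k2*C, So*N)
  dX <- .col2im_cpp(dPatch, plan$P0, cache$C, plan$S, cache$N)
  list(dW = dW, db = db, dX = dX)
}

# Channel counts and strides of the conv stack, from the model config.
conv_stack_geometry <- function(config) {
  channels <- c(config$in_channels, config$conv_channels,
                config$final_channels)
  strides <- c(config$conv_strides %||% rep(2L, length(config$conv_channels)),
               1L)
  sizes <- config$resolution
  for (s in strides) sizes <- c(sizes, tail(sizes, 1L) %/% s)
  list(channels = channels, strides = strides,
       sizes = sizes[-length(sizes)])  # input size of each layer
}

# Forward through the conv stack. X: (C, S*N) channel-first input images.
# Returns the post-ReLU final maps A as a (So, K, N) array (the Grad-CAM
# layout), pooled vectors (K, N) and per-layer caches.
conv_stack_forward <- function(weights, config, X) {
  geo <- conv_stack_geometry(config)
  nl <- length(geo$strides)
  N <- ncol(X) %/% (geo$sizes[1L]^2)
  caches <- vector("list", nl)
  cur <- X
  for (l in seq_len(nl)) {
    plan <- conv_plan_cached(geo$sizes[l], geo$sizes[l], geo$strides[l])
    cf <- conv_forward(weights[[paste0("conv", l, "_W")]],
                       weights[[paste0("conv", l, "_b")]], cur,
                       geo$channels[l], N, plan)
    cur <- cf$pre
    cur[cur < 0] <- 0
    caches[[l]] <- list(cf = cf, plan = plan, mask = cf$pre > 0)
  }
  K <- nrow(cur)
  So <- caches[[nl]]$plan$So
  dim(cur) <- c(K, So, N)
  A <- aperm(cur, c(2L, 1L, 3L))                  # (So, K, N) post-ReLU
  pooled <- colMeans(A)                           # (K, N) global average
  list(A = A, pooled = pooled, caches = caches)
}

# Backward through the conv stack from dPooled (K, N); adds conv weight
# grads into `grads` (an environment).
conv_stack_backward <- function(weights, config, caches, dPooled, grads) {
  nl <- length(caches)
  plan <- caches[[nl]]$plan
  N <- caches[[nl]]$cf$N
  # GAP backward: uniform 1/So over spatial positions of each image
  dPre <- dPooled[, rep(seq_len(N), each = plan$So), drop = FALSE] / plan$So
  dPre <- dPre * caches[[nl]]$mask
  for (l in rev(seq_len(nl))) {
    plan <- caches[[l]]$plan
    cb <- conv_backward(weights[[paste0("conv", l, "_W")]], dPre,
                        caches[[l]]$cf, plan)
    grads[[paste0("conv", l, "_W")]] <- grads[[paste0("conv", l, "_W")]] + cb$dW
    grads[[paste0("conv", l, "_b")]] <- grads[[paste0("conv", l, "_b")]] + cb$db
    if (l > 1L)  # dX already matches the previous layer's (K, So*N) layout
      dPre <- cb$dX * caches[[l - 1L]]$mask
  }
  invisible(NULL)
}

# Random-erasing augmentation on a channel-first batch (C, S*nimg):
# replaces a random rectangle of each selected view by background pixels
# (normals 0.5, depth 1). Uses the caller's RNG stream.
erase_views <- function(X, H, prob, frac = c(0.2, 0.5)) {
  S <- H * H
  nimg <- ncol(X) %/% S
  for (n in seq_len(nimg)) {
    if (stats::runif(1) >= prob) next
    hgt <- max(1L, round(stats::runif(1, frac[1], frac[2]) * H))
    wdt <- max(1L, round(stats::runif(1, frac[1], frac[2]) * H))
    r0 <- sample.int(H - hgt + 1L, 1L)
    c0 <- sample.int(H - wdt + 1L, 1L)
    idx <- as.vector(outer(r0:(r0 + hgt - 1L),
                           (c0:(c0 + wdt - 1L) - 1L) * H, `+`)) +
      (n - 1L) * S
    X[1:3, idx] <- 0.5
    X[4, idx] <- 1
  }
  X
}

# Gated attention scorer over the views of each mesh.
# P: (D, V, B). Returns weights a (V, B), aggregate z (D, B) and caches.
attn_forward <- function(weights, P) {
  D <- dim(P)[1L]; V <- dim(P)[2L]; B <- dim(P)[3L]
  Pm <- P
  dim(Pm) <- c(D, V * B)
  Uh <- tanh(weights$attn_V %*% Pm + weights$attn_bV)
  G <- 1 / (1 + exp(-(weights$attn_U %*% Pm + weights$attn_bU)))
  scores <- matrix(crossprod(weights$attn_w, Uh * G), V, B)
  smax <- apply(scores, 2L, max)
  e <- exp(sweep(scores, 2L, smax))
  a <- sweep(e, 2L, colSums(e), "/")
  z <- matrix(0, D, B)
  for (b in seq_len(B))
    z[, b] <- Pm[, (b - 1L) * V + seq_len(V), drop = FALSE] %*% a[, b]
  list(a = a, z = z, Uh = Uh, G = G, P = P, Pm = Pm, V = V, B = B, D = D)
}

# dz: (D, B). Adds attention parameter grads into `grads`; returns dP
# (D, V, B), the gradient at the pooled per-view features.
attn_backward <- function(weights, cache, dz, grads) {
  D <- cache$D; V <- cache$V; B <- cache$B
  a <- cache$a
  da <- matrix(0, V, B)
  dP <- array(0, c(D, V, B))
  for (b in seq_len(B)) {
    cols <- (b - 1L) * V + seq_len(V)
    da[, b] <- crossprod(cache$Pm[, cols, drop = FALSE], dz[, b])
    dP[, , b] <- dz[, b] %o% a[, b]               # direct path z = P a
  }
  ds <- a * sweep(da, 2L, colSums(a * da))        # softmax backward
  dsm <- matrix(ds, V, B)
  dUG <- weights$attn_w %o% as.vector(dsm)        # (h, V*B)
  du <- dUG * cache$G
  dg <- dUG * cache$Uh
  dpre_u <- du * (1 - cache$Uh^2)
  dpre_g <- dg * cache$G * (1 - cache$G)
  grads$attn_V <- grads$attn_V + dpre_u %*% t(cache$Pm)
  grads$attn_bV <- grads$attn_bV + rowSums(dpre_u)
  grads$attn_U <- grads$attn_U + dpre_g %*% t(cache$Pm)
  grads$attn_bU <- grads$attn_bU + rowSums(dpre_g)
  grads$attn_w <- grads$attn_w +
    as.vector((cache$Uh * cache$G) %*% as.vector(dsm))
  dPm <- crossprod(weights$attn_V, dpre_u) + crossprod(weights$attn_U, dpre_g)
  dim(dPm) <- c(D, V, B)
  dP + dPm
}

softmax_cols <- function(x) {
  e <- exp(sweep(x, 2L, apply(x, 2L, max)))
  sweep(e, 2L, colSums(e), "/")
}

# Full forward pass: X (S, C, V*B) stacked view images for B meshes.
mvcnn_forward <- function(weights, config, X, V, B) {
  enc <- conv_stack_forward(weights, config, X)
  P <- enc$pooled
  dim(P) <- c(nrow(enc$pooled), V, B)
  at <- attn_forward(weights, P)
  logits <- weights$cls_W %*% at$z + weights$cls_b
  list(logits = logits, probs = softmax_cols(logits), attn = at$a,
       enc = enc, at = at, V = V, B = B)
}

# Full backward from dlogits (4, B); returns a named list of parameter
# gradients matching the weight list.
mvcnn_backward <- function(weights, config, fw, dlogits) {
  grads <- new.env(parent = emptyenv())
  for (nm in names(weights)) grads[[nm]] <- weights[[nm]] * 0
  grads$cls_W <- dlogits %*% t(fw$at$z)
  grads$cls_b <- rowSums(dlogits)
  dz <- crossprod(weights$cls_W, dlogits)
  dP <- attn_backward(weights, fw$at, dz, grads)
  dPooled <- dP
  dim(dPooled) <- c(dim(dP)[1L], fw$V * fw$B)
  conv_stack_backward(weights, config, fw$enc$caches, dPooled, grads)
  as.list(grads)
}

# Head-only forward: from given post-ReLU final conv maps A (So, K, V) of a
# single mesh to the 4 logits. Used by Grad-CAM and its finite-difference
# oracle: the class score is a function of the final feature maps through
# global average pooling, the attention layer and the classifier.
head_forward <- function(weights, A) {
  pooled <- colMeans(A)                            # (K, V)
  P <- pooled
  dim(P) <- c(dim(P), 1L)
  at <- attn_forward(weights, P)
  logits <- as.vector(weights$cls_W %*% at$z + weights$cls_b)
  list(logits = logits, at = at)
}

# Gradient of one class logit w.r.t. the final conv maps A (So, K, V).
# The gradient flows through the attention weighting (each view's
# contribution to the logit), so per-view channel importances differ.
head_grad <- function(weights, A, class_idx) {
  hf <- head_forward(weights, A)
  dlogits <- matrix(0, nrow(weights$cls_W), 1L)
  dlogits[class_idx + 1L, 1L] <- 1
  grads <- new.env(parent = emptyenv())
  for (nm in c("attn_V", "attn_bV", "attn_U", "attn_bU", "attn_w"))
    grads[[nm]] <- weights[[nm]] * 0
  dz <- crossprod(weights$cls_W, dlogits)
  dP <- attn_backward(weights, hf$at, dz, grads)   # (K, V, 1)
  So <- dim(A)[1L]
  dPooled <- dP[, , 1L, drop = TRUE]               # (K, V)
  if (is.null(dim(dPooled))) dPooled <- matrix(dPooled, ncol = dim(A)[3L])
  # GAP spreads each pooled gradient uniformly over spatial positions
  dA <- array(0, dim(A))
  for (v in seq_len(dim(A)[3L]))
    dA[, , v] <- matrix(dPooled[, v], So, dim(A)[2L], byrow = TRUE) / So
  list(dA = dA, logits = hf$logits)
}

# Adam optimizer step over a named list of parameters, with decoupled
# weight decay (biases exempt).
adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !grepl("_b[UV]?$", nm))
      upd <- upd + weight_decay * weights[[nm]]
    weights[[nm]] <- weights[[nm]] - lr * upd
  }
  list(weights = weights, state = state)
}

adam_init <- function(weights) {
  list(t = 0L,
       m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0))
}
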