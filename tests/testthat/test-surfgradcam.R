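test_that("CAMs are zero when the class logit ignores a view's features", {
  model <- toy_model(32L)
  mesh <- normalize_pose(build_arch(sample_params(1, 4))$mesh)
  views <- render_all(mesh, default_views(), 32)
  # a classifier row of zeros makes every gradient (and CAM) vanish
  model$weights$cls_W[3, ] <- 0
  cam <- gradcam_view(model, views, target_class = 2, view_index = 1)
  expect_true(all(cam$values == 0))
  expect_error(gradcam_view(model, views, 7, 1), "target_class")
  expect_error(gradcam_view(model, views, 1, 99), "view_index")
})

test_that("single-channel toy model reduces the CAM to gradient x activation", {
  cfg <- mvcnn_config(resolution = 16L, conv_channels = c(2L),
                      final_channels = 1L, attn_hidden = 3L, seed = 10)
  model <- mvcnn_init(cfg)
  sg <- asNamespace("surfgradcam")
  set.seed(11)
  A <- array(abs(rnorm(64 * 1 * 2)), c(64, 1, 2))    # (So, K=1, V=2)
  hg <- sg$head_grad(model$weights, A, 1L)
  cams <- sg$gradcam_cams(model, A, 1L, 16L)
  for (v in 1:2) {
    g <- mean(hg$dA[, , v])                          # uniform gradient
    expected <- pmax(matrix(A[, 1, v] * g, 8, 8), 0)
    expect_equal(cams[[v]]$small, expected, tolerance = 1e-12)
  }
})

test_that("gradients behind the CAM match central finite differences", {
  cfg <- mvcnn_config(resolution = 16L, conv_channels = c(3L),
                      final_channels = 5L, attn_hidden = 4L, seed = 21)
  model <- mvcnn_init(cfg)
  sg <- asNamespace("surfgradcam")
  set.seed(22)
  V <- 3L
  A <- array(abs(rnorm(64 * 5 * V)), c(64, 5, V))
  for (cl in c(0L, 3L)) {
    hg <- sg$head_grad(model$weights, A, cl)
    eps <- 1e-3
    set.seed(23 + cl)
    for (t in 1:40) {
      i <- sample(64, 1); k <- sample(5, 1); v <- sample(V, 1)
      Ap <- A; Ap[i, k, v] <- A[i, k, v] + eps
      Am <- A; Am[i, k, v] <- A[i, k, v] - eps
      fd <- (sg$head_forward(model$weights, Ap)$logits[cl + 1] -
             sg$head_forward(model$weights, Am)$logits[cl + 1]) / (2 * eps)
      expect_equal(hg$dA[i, k, v], fd, tolerance = 1e-4)
    }
    # channel weights = spatial average of the gradients, per view
    for (v in seq_len(V)) {
      alpha <- colMeans(hg$dA[, , v])
      fd_alpha <- numeric(5)
      for (k in 1:5) {
        Ap <- A; Ap[, k, v] <- A[, k, v] + eps
        Am <- A; Am[, k, v] <- A[, k, v] - eps
        fd_alpha[k] <- (sg$head_forward(model$weights, Ap)$logits[cl + 1] -
                        sg$head_forward(model$weights, Am)$logits[cl + 1]) /
          (2 * eps) / 64
      }
      expect_equal(alpha, fd_alpha, tolerance = 1e-4)
    }
  }
})

test_that("surface pooling takes the max over pixels, views, incident faces", {
  # two synthetic views over a 2-face mesh, hand-built face-id buffers
  mesh <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  mk_view <- function(fid) {
    structure(list(face_id = fid, resolution = 2L,
                   channels = array(0, c(2, 2, 4)),
                   camera = list(id = 1L)), class = "rendered_view")
  }
  mk_cam <- function(vals) {
    structure(list(values = vals, small = vals, view_index = 1L,
                   target_class = 0L), class = "class_activation_map")
  }
  v1 <- mk_view(matrix(c(1L, 1L, 0L, 0L), 2))
  c1 <- mk_cam(matrix(c(0.2, 0.7, 9, 9), 2))   # face 1 pixels: 0.2, 0.7
  hm1 <- pool_to_surface(list(c1), list(v1), mesh)
  expect_equal(hm1$face_values, c(0.7, 0))
  # vertex 4 only touches the unseen face -> exactly 0
  expect_equal(hm1$vertex_values, c(0.7, 0.7, 0.7, 0))
  # across views: face seen twice keeps the larger view maximum
  v2 <- mk_view(matrix(c(1L, 0L, 2L, 0L), 2))
  c2 <- mk_cam(matrix(c(0.9, 0, 0.4, 0), 2))
  hm2 <- pool_to_surface(list(c1, c2), list(v1, v2), mesh)
  expect_equal(hm2$face_values, c(0.9, 0.4))
  expect_equal(hm2$normalized, hm2$vertex_values / 0.9)
  # adding a view never decreases any face value (max-pool monotonicity)
  expect_true(all(hm2$face_values >= hm1$face_values))
  # mean vertex pooling as the documented alternative
  hm3 <- pool_to_surface(list(c1), list(v1), mesh, vertex_pool = "mean")
  expect_equal(hm3$vertex_values, c(0.7, 0.35, 0.35, 0))
  bad <- mk_cam(matrix(0, 3, 3))
  expect_error(pool_to_surface(list(bad), list(v1), mesh), "mismatch")
})

test_that("max-pool monotonicity holds on rendered meshes", {
  model <- toy_model(32L)
  mesh <- normalize_pose(build_arch(sample_params(3, 12))$mesh)
  views <- render_all(mesh, default_views(), 32)
  x <- surfgradcam:::views_to_tensor(views)
  enc <- surfgradcam:::conv_stack_forward(model$weights, model$config,
                                          surfgradcam:::flatten_views(x))
  cams <- surfgradcam:::gradcam_cams(model, enc$A, 0L, 32L)
  for (k in c(3L, 8L, 12L)) {
    hk <- pool_to_surface(cams[seq_len(k)], views[seq_len(k)], mesh)
    if (k > 3L)
      expect_true(all(hk$face_values >= h_prev$face_values - 1e-12))
    h_prev <- hk
  }
  # all-zero CAMs stay all-zero after normalization
  zero_cams <- lapply(cams, function(cm) { cm$values[] <- 0; cm })
  hz <- pool_to_surface(zero_cams, views, mesh)
  expect_true(all(hz$normalized == 0))
})

test_that("explain attaches one named heatmap array per severity grade", {
  model <- toy_model(32L)
  mesh <- build_arch(sample_params(2, 18))$mesh
  out <- explain(mesh, model, target_classes = 0:3,
                 viewset = default_views())
  expect_setequal(names(out$vertex_scalars),
                  paste0("surfgradcam_class", 0:3))
  for (nm in names(out$vertex_scalars)) {
    v <- out$vertex_scalars[[nm]]
    expect_length(v, n_vertices(out))
    expect_true(all(v >= 0 & v <= 1))
  }
  out2 <- explain(mesh, model, target_classes = 0:3,
                  viewset = default_views())
  expect_identical(out$vertex_scalars, out2$vertex_scalars)
  # heatmap meshes survive a VTK round trip with their arrays
  f <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(f, out)
  back <- read_mesh(f)
  expect_setequal(names(back$vertex_scalars),
                  paste0("surfgradcam_class", 0:3))
})
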