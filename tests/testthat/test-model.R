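test_that("encoder is zero-preserving and positively homogeneous at init", {
  model <- toy_model(32L)
  zero <- array(0, c(32, 32, 4))
  enc <- encode_view(model, zero)
  # biases are zero at init, so a zero image yields zero feature maps
  expect_true(all(enc$conv_maps == 0))
  expect_true(all(enc$pooled == 0))
  set.seed(2)
  img <- array(abs(rnorm(32 * 32 * 4)), c(32, 32, 4))
  e1 <- encode_view(model, img)
  e2 <- encode_view(model, img)
  expect_identical(e1$conv_maps, e2$conv_maps)   # determinism
  # conv + ReLU with zero biases is positively homogeneous
  e3 <- encode_view(model, img * 2)
  expect_equal(e3$conv_maps, e1$conv_maps * 2, tolerance = 1e-12)
  expect_error(encode_view(model, array(0, c(16, 16, 4))), "image must be")
})

test_that("attention weights live on the simplex and are permutation-consistent", {
  model <- toy_model()
  set.seed(5)
  D <- model$config$final_channels
  # singleton: weight 1, aggregate = input
  p1 <- matrix(rnorm(D), D, 1)
  a1 <- attention_aggregate(model, p1)
  expect_equal(a1$weights, 1)
  expect_equal(a1$aggregated, as.vector(p1))
  # identical views: uniform weights
  pid <- matrix(rnorm(D), D, 6)[, rep(1, 6)]
  aid <- attention_aggregate(model, pid)
  expect_equal(aid$weights, rep(1 / 6, 6), tolerance = 1e-12)
  # random view sets: simplex invariant + permutation equivariance
  for (rep in 1:20) {
    P <- matrix(rnorm(D * 8), D, 8)
    ag <- attention_aggregate(model, P)
    expect_true(all(ag$weights >= 0))
    expect_equal(sum(ag$weights), 1, tolerance = 1e-6)
    perm <- sample(8)
    agp <- attention_aggregate(model, P[, perm])
    expect_equal(agp$weights, ag$weights[perm], tolerance = 1e-12)
    expect_equal(agp$aggregated, ag$aggregated, tolerance = 1e-12)
  }
  expect_error(attention_aggregate(model, matrix(0, 8, 0)), "view")
})

test_that("classifier head produces coherent softmax probabilities", {
  model <- toy_model()
  D <- model$config$final_channels
  model$weights$cls_W[] <- 0
  model$weights$cls_b[] <- 0
  out <- classify(model, rnorm(D))
  expect_equal(out$probs, rep(0.25, 4))
  model$weights$cls_b <- c(10, 0, 0, 0)
  expect_equal(which.max(classify(model, rep(0, D))$probs), 1L)
  model2 <- toy_model()
  set.seed(8)
  for (i in 1:200) {
    out <- classify(model2, rnorm(D) * 10)
    expect_equal(sum(out$probs), 1, tolerance = 1e-9)
    expect_true(all(out$probs >= 0))
    expect_equal(which.max(out$probs), which.max(out$logits))
  }
})

test_that("mesh prediction is deterministic and view-permutation invariant", {
  model <- toy_model()
  mesh <- build_arch(sample_params(2, 6))$mesh
  vs <- icosphere_cameras(0, 3)
  p1 <- predict(model, mesh, vs)
  p2 <- predict(model, mesh, vs)
  expect_identical(p1$probs, p2$probs)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-9)
  # permuting the cameras permutes attention but not the prediction
  perm <- c(5, 1, 12, 3, 8, 2, 10, 7, 4, 11, 6, 9)
  vsp <- vs
  vsp$cameras <- vs$cameras[perm]
  p3 <- predict(model, mesh, vsp)
  expect_equal(p3$probs, p1$probs, tolerance = 1e-10)
  expect_equal(p3$attention, p1$attention[perm], tolerance = 1e-10)
})

test_that("training overfits a tiny separable set and respects epochs = 0", {
  man <- generate_dataset(2L, withr::local_tempdir(), seed = 33)
  vs <- icosphere_cameras(0, 3)
  data <- render_dataset(man, vs, 32)
  cfg <- mvcnn_config(resolution = 32L, conv_channels = c(8L, 16L),
                      final_channels = 16L, epochs = 0L, seed = 2)
  m0 <- train_mvcnn(data, cfg)
  expect_identical(m0$weights, mvcnn_init(cfg)$weights)
  # 8 meshes in one batch: epochs = optimizer steps, so give it enough
  cfg$epochs <- 250L
  m1 <- train_mvcnn(data, cfg)
  pt <- max.col(surfgradcam:::predict_prob_matrix(m1, data$x)) - 1L
  expect_equal(mean(pt == data$labels), 1)        # 8 shapes, 2 per class
  expect_equal(nrow(m1$log), 250L)
  # reproducibility of the whole training trajectory
  m2 <- train_mvcnn(data, cfg)
  expect_equal(m2$log, m1$log, tolerance = 1e-12)
  expect_equal(m2$weights$cls_W, m1$weights$cls_W, tolerance = 1e-12)
})

test_that("a class missing from the training split warns and is down-weighted", {
  man <- generate_dataset(2L, withr::local_tempdir(), seed = 14)
  data <- render_dataset(man, icosphere_cameras(0, 3), 32)
  cfg <- mvcnn_config(resolution = 32L, conv_channels = c(4L),
                      final_channels = 8L, epochs = 1L, seed = 3)
  expect_warning(m <- train_mvcnn(data, cfg, train_idx = which(data$labels != 3)),
                 "absent")
  expect_equal(m$class_weights[4], 0)
})

test_that("checkpoints round-trip the model", {
  model <- toy_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  m2 <- load_checkpoint(f)
  expect_s3_class(m2, "mvcnn")
  expect_equal(m2$weights, model$weights)
  expect_equal(m2$config$seed, model$config$seed)
})
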