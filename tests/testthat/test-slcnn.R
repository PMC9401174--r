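test_that("convolution output length follows the valid-mode formula", {
  expect_equal(conv_output_length(10, 3, 1), 8L)
  expect_equal(conv_output_length(10, 3, 2), 4L) # starts at bins 0, 2, 4, 6
  expect_equal(conv_output_length(5, 5, 1), 1L)
  expect_error(conv_output_length(4, 5, 1), "exceed")
})

test_that("1D convolution matches hand values and the loop oracle", {
  cfg <- slcnn_config(K_spec = 1, N_spec = 2, stride_s = 1)
  m <- slcnn_from_weights(cfg, list(C = 1, P = 3),
                          W_spec = matrix(c(1, 1), 1), b_spec = 0,
                          V = matrix(0, 2, 2), b_out = c(0, 0),
                          label_levels = c("a", "b"))
  expect_equal(as.vector(conv1d_forward(c(1, 2, 3), m, "identity")), c(3, 5))
  expect_equal(as.vector(conv1d_forward(c(1, 2, 3), m)), c(3, 5))

  m2 <- slcnn_from_weights(cfg, list(C = 1, P = 3),
                           W_spec = matrix(c(1, -1), 1), b_spec = 0,
                           V = matrix(0, 2, 2), b_out = c(0, 0),
                           label_levels = c("a", "b"))
  expect_equal(as.vector(conv1d_forward(c(3, 1, 2), m2, "identity")), c(2, -1))
  expect_equal(as.vector(conv1d_forward(c(3, 1, 2), m2)), c(2, 0))

  # all-zero weights give an all-zero map
  m3 <- slcnn_from_weights(cfg, list(C = 1, P = 3),
                           W_spec = matrix(c(0, 0), 1), b_spec = 0,
                           V = matrix(0, 2, 2), b_out = c(0, 0),
                           label_levels = c("a", "b"))
  expect_equal(as.vector(conv1d_forward(c(5, -2, 7), m3)), c(0, 0))

  # random multi-channel cases against the loop oracle
  for (seed in 1:5) {
    withr::with_seed(seed, {
      C <- sample(1:3, 1); P <- sample(8:15, 1)
      N <- sample(2:4, 1); s <- sample(1:3, 1); K <- sample(1:3, 1)
      W <- matrix(rnorm(K * C * N), K); b <- rnorm(K)
      x <- matrix(rnorm(C * P), C)
      cfg <- slcnn_config(K_spec = K, N_spec = N, stride_s = s)
      mm <- slcnn_from_weights(cfg, list(C = C, P = P), W, b,
                               V = matrix(0, K * conv_output_length(P, N, s), 2),
                               b_out = c(0, 0), label_levels = c("a", "b"))
      expect_equal(conv1d_forward(x, mm), oracle_conv1d(x, W, b, s),
                   ignore_attr = TRUE, tolerance = 1e-12)
    })
  }
})

test_that("2D convolution + max pooling matches the loop oracle", {
  # hand case: max pooling of [[1,2],[3,4]] with window 2 is 4
  expect_equal(max(matrix(1:4, 2)), 4)
  for (seed in 1:4) {
    withr::with_seed(seed, {
      Cg <- sample(1:2, 1); H <- sample(5:7, 1); Wd <- sample(5:7, 1)
      N <- 2; pool <- 2; K <- 2
      W <- matrix(rnorm(K * Cg * N * N), K); b <- rnorm(K)
      imgs <- purrr::map(seq_len(Cg), ~ matrix(rnorm(H * Wd), H))
      names(imgs) <- paste0("ct", seq_len(Cg))
      cfg <- slcnn_config(K_spec = 1, N_spec = 2, stride_s = 1,
                          K_img = K, N_img = N, pool_size = pool)
      d_spec <- conv_output_length(10, 2, 1)
      d_img <- K * ((H - N + 1) %/% pool) * ((Wd - N + 1) %/% pool)
      mm <- slcnn_from_weights(
        cfg, list(C = 1, P = 10, contrasts = names(imgs), H = H, W = Wd),
        W_spec = matrix(0, 1, 2), b_spec = 0,
        V = matrix(0, d_spec + d_img, 2), b_out = c(0, 0),
        W_img = W, b_img = b, label_levels = c("a", "b")
      )
      expect_equal(conv2d_pool_forward(imgs, mm),
                   oracle_conv2d_pool(imgs, W, b, N, pool),
                   ignore_attr = TRUE, tolerance = 1e-12)
    })
  }
  # branch disabled
  m <- random_model(1)
  expect_error(conv2d_pool_forward(list(T1 = matrix(0, 4, 4)), m),
               "image branch disabled")
})

test_that("merge/flatten layout matches the feature index map", {
  spec_map <- matrix(1:16, 2, 8, byrow = TRUE)
  img_map <- matrix(101:112, 3, 4, byrow = TRUE)
  v <- merge_flatten(spec_map, img_map)
  expect_length(v, 28)
  expect_length(merge_flatten(spec_map), 16)
  # merged feature 0 is spectral kernel 0 position 0
  expect_equal(v[1], spec_map[1, 1])
  expect_equal(v[9], spec_map[2, 1]) # feature index 8 = kernel 1, position 0

  m <- random_model(3, with_images = TRUE)
  fmap <- feature_index_map(m)
  expect_equal(fmap$feature, seq_len(nrow(fmap)) - 1L)
  expect_equal(fmap$branch[1], "spectral")
  expect_equal(fmap$kernel[1], 0L)
  expect_equal(fmap$position[1], 0L)
  expect_true(any(fmap$branch == "image"))
  # merged features from the ops agree with the model forward pass
  ds <- simulate_dataset(quick_cfg(seed = 5, n_pat = 2, n_vox = 2, P = 20,
                                   image_shape = c(5, 5)))
  Phi <- conv_features(m, ds)
  x1 <- ds$spectra[1, , , drop = TRUE]
  imgs <- list(T1 = ds$images$T1[1, , ])
  manual <- merge_flatten(conv1d_forward(x1, m), conv2d_pool_forward(imgs, m))
  expect_equal(unname(Phi[1, ]), manual)
})

test_that("prediction is a softmax: non-negative, sums to one, seedless", {
  m <- random_model(11, n_classes = 3)
  ds <- simulate_dataset(quick_cfg(seed = 2, n_pat = 2, n_vox = 3, P = 20))
  p <- predict(m, ds, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, n_voxels(ds)), tolerance = 1e-9)

  # zero output layer gives uniform probabilities
  m0 <- m
  m0$V[] <- 0; m0$b_out[] <- 0
  expect_equal(unname(predict(m0, ds, type = "prob")),
               matrix(1 / 3, n_voxels(ds), 3))

  # identical samples, identical probabilities
  meta2 <- tibble::tibble(voxel_id = c("dup1", "dup2"),
                          patient_id = c("p1", "p1"),
                          label = c("neg", "neg"))
  spec2 <- ds$spectra[c(1, 1), , , drop = FALSE]
  ds2 <- mrsi_dataset(meta2, spec2, label_levels = c("neg", "pos"))
  p2 <- predict(m, ds2, type = "prob")
  expect_equal(p2[1, ], p2[2, ])
})

test_that("smoothness penalty matches hand values and invariances", {
  expect_equal(smoothness_penalty(matrix(rep(3, 5), 1)), 0)
  expect_equal(smoothness_penalty(matrix(c(0, 1, 0), 1)), 2)
  expect_equal(smoothness_penalty(rbind(c(0, 1, 0), c(1, 1, 1))), 2)

  # adding a constant to one kernel leaves the penalty unchanged
  W <- matrix(rnorm(8), 2)
  expect_equal(smoothness_penalty(W), smoothness_penalty(W + 5))
  expect_gt(smoothness_penalty(W), 0)

  # 2D: horizontal and vertical neighbor pairs
  cfg <- slcnn_config(K_spec = 1, N_spec = 2, stride_s = 1,
                      K_img = 1, N_img = 2, pool_size = 1)
  grid <- matrix(c(0, 1, 2, 4), 2) # column-major: pairs (0,1),(2,4),(0,2),(1,4)
  m <- slcnn_from_weights(
    cfg, list(C = 1, P = 4, contrasts = "T1", H = 3, W = 3),
    W_spec = matrix(c(2, 2), 1), b_spec = 0,
    V = matrix(0, 1 * 3 + 1 * 4, 2), b_out = c(0, 0),
    W_img = matrix(as.vector(grid), 1), b_img = 0,
    label_levels = c("a", "b")
  )
  expect_equal(smoothness_penalty(m), (1 - 0)^2 + (4 - 2)^2 + (2 - 0)^2 + (4 - 1)^2)
})

test_that("loss decomposes into weighted cross-entropy plus penalties", {
  ds <- simulate_dataset(quick_cfg(seed = 6, n_pat = 2, n_vox = 3, P = 20,
                                   image_shape = c(5, 5)))
  m <- random_model(21, with_images = TRUE)
  m$label_levels <- c("neg", "pos")
  l0 <- slcnn_loss(m, ds, lambda1 = 0, lambda2 = 0, class_weighting = FALSE)
  p <- predict(m, ds, type = "prob")
  ce <- mean(-log(p[cbind(seq_len(n_voxels(ds)),
                          match(ds$meta$label, m$label_levels))]))
  expect_equal(l0, ce, tolerance = 1e-10)

  # doubling lambda2 adds exactly one smoothness penalty
  l1 <- slcnn_loss(m, ds, lambda1 = 0, lambda2 = 1, class_weighting = FALSE)
  l2 <- slcnn_loss(m, ds, lambda1 = 0, lambda2 = 2, class_weighting = FALSE)
  expect_equal(l2 - l1, smoothness_penalty(m), tolerance = 1e-8)

  # lambda1 adds the squared-weight penalty over conv + output weights
  l3 <- slcnn_loss(m, ds, lambda1 = 1, lambda2 = 0, class_weighting = FALSE)
  expect_equal(l3 - l0, sum(m$W_spec^2) + sum(m$W_img^2) + sum(m$V^2),
               tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  ds <- simulate_dataset(quick_cfg(seed = 8, n_pat = 2, n_vox = 3, P = 18,
                                   image_shape = c(5, 5)))
  for (with_img in c(FALSE, TRUE)) {
    m <- random_model(31 + with_img, P = 18, with_images = with_img,
                      H = 5, Wd = 5)
    m$label_levels <- c("neg", "pos")
    dsx <- ds
    if (!with_img) dsx$images <- list()
    design <- mrsiclass:::slcnn_design(dsx, m$config, m$dims)
    y_idx <- match(ds$meta$label, m$label_levels)
    w <- mrsiclass:::class_weight_vector(ds$meta$label, m$label_levels, TRUE)
    res <- mrsiclass:::slcnn_loss_grad(m, design, y_idx, w, 0.01, 0.02)
    gv <- mrsiclass:::grads_to_vector(res$grads, with_img)
    p0 <- mrsiclass:::flatten_params(m)
    f <- function(v) mrsiclass:::slcnn_loss_grad(
      mrsiclass:::set_params(m, v), design, y_idx, w, 0.01, 0.02,
      compute_grad = FALSE)$loss
    fd <- fd_grad(f, p0)
    expect_lt(max(abs(gv - fd) / pmax(abs(fd), 1e-4)), 1e-5)
  }
})

test_that("training is seeded, convergent on separable data, and guarded", {
  cfg <- quick_cfg(seed = 12, n_pat = 3, n_vox = 5, effect = 2.5,
                   patient_sd = 0, noise = 0, P = 32)
  ds <- simulate_dataset(cfg)
  mcfg <- slcnn_config(K_spec = 3, N_spec = 8, stride_s = 2, epochs = 40,
                       eta = 0.1, batch_size = 10, seed = 1)
  for (sd in 1:3) {
    mcfg$seed <- sd
    m <- slcnn_train(ds, mcfg)
    expect_equal(mcc(ds$meta$label, predict(m, ds)$predicted), 1.0)
  }

  # identical seed, identical weights; different seed differs
  m1 <- slcnn_train(ds, mcfg)
  m2 <- slcnn_train(ds, mcfg)
  expect_identical(m1$W_spec, m2$W_spec)
  expect_identical(m1$V, m2$V)
  mcfg2 <- mcfg; mcfg2$seed <- 99L
  expect_false(identical(slcnn_train(ds, mcfg2)$W_spec, m1$W_spec))

  # loss trace recorded and finite
  expect_length(m1$loss_trace, 40)
  expect_true(all(is.finite(m1$loss_trace)))

  # exploding learning rate is reported with the epoch
  bad <- slcnn_config(K_spec = 3, N_spec = 8, stride_s = 2, epochs = 30,
                      eta = 1e4, batch_size = 10)
  expect_error(slcnn_train(ds, bad), "epoch .*eta")

  expect_error(
    slcnn_train(subset_voxels(ds, ds$meta$label == "neg"), mcfg),
    ">= 2 classes"
  )
})

test_that("the smoothness regularizer flattens learned kernels", {
  sm_high <- sm_zero <- numeric(5)
  for (sd in 1:5) {
    ds <- simulate_dataset(quick_cfg(seed = sd, n_pat = 3, n_vox = 4, P = 32))
    base <- slcnn_config(K_spec = 2, N_spec = 8, stride_s = 2, epochs = 60,
                         eta = 0.01, batch_size = 8, seed = sd)
    base$lambda2 <- 0
    sm_zero[sd] <- smoothness_penalty(slcnn_train(ds, base))
    base$lambda2 <- 10
    sm_high[sd] <- smoothness_penalty(slcnn_train(ds, base))
  }
  expect_true(all(sm_high < sm_zero))
})

test_that("receptive-field locality holds under finite differencing", {
  # identity activation isolates the linear convolution geometry
  for (seed in 1:6) {
    m <- random_model(seed, P = 15 + seed, K = 2, N = 3 + seed %% 3,
                      s = 1 + seed %% 3)
    N <- m$config$N_spec; s <- m$config$stride_s; P <- m$dims$P
    x <- withr::with_seed(seed + 100, rnorm(P))
    base <- conv1d_forward(x, m, "identity")
    b <- sample.int(P, 1) - 1L # 0-based perturbed bin
    x2 <- x; x2[b + 1] <- x2[b + 1] + 1
    delta <- abs(conv1d_forward(x2, m, "identity") - base) > 1e-12
    for (j in seq_len(ncol(base)) - 1L) {
      inside <- (j * s <= b) && (b <= j * s + N - 1)
      expect_identical(unname(any(delta[, j + 1])), inside)
    }
  }
})

test_that("models serialize to JSON and back without changing predictions", {
  ds <- simulate_dataset(quick_cfg(seed = 14, n_pat = 2, n_vox = 3, P = 24,
                                   image_shape = c(5, 5)))
  cfg <- slcnn_config(K_spec = 2, N_spec = 6, stride_s = 3, K_img = 2,
                      N_img = 2, pool_size = 2, epochs = 10, seed = 5)
  m <- slcnn_train(ds, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_slcnn(m, path)
  back <- read_slcnn(path)
  expect_equal(predict(back, ds, type = "prob"), predict(m, ds, type = "prob"))
  expect_equal(back$W_spec, m$W_spec)
})
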