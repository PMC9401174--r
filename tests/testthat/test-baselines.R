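make_blob_datasets <- function(seed, sep = 6) {
  withr::with_seed(seed, {
    n <- 20
    X <- rbind(matrix(rnorm(n * 8), n), matrix(rnorm(n * 8, mean = sep), n))
    meta <- tibble::tibble(
      voxel_id = paste0("v", seq_len(2 * n)),
      patient_id = paste0("p", seq_len(2 * n)),
      label = rep(c("a", "b"), each = n)
    )
    ds <- mrsi_dataset(meta, array(X, dim = c(2 * n, 1, 8)))
    idx <- sample(2 * n)
    list(train = subset_voxels(ds, idx[1:30]), test = subset_voxels(ds, idx[31:40]))
  })
}

test_that("RBF SVM separates distant blobs and scores consistently", {
  blobs <- make_blob_datasets(1)
  out <- svm_rbf_classify(blobs$train, blobs$test, C = 1, gamma = 0.1)
  expect_equal(out$predicted, out$truth)
  # decision scores orient toward the positive (second) class
  expect_true(all(out$score_b[out$truth == "b"] > 0))
  expect_true(all(out$score_b[out$truth == "a"] < 0))
  expect_equal(out$score_a, -out$score_b)

  # huge gamma memorizes the training set
  mem <- svm_rbf_classify(blobs$train, blobs$train, C = 10, gamma = 100)
  expect_equal(mem$predicted, mem$truth)

  single <- subset_voxels(blobs$train, blobs$train$meta$label == "a")
  expect_error(svm_rbf_classify(single, blobs$test), "single class")
})

test_that("PLS-DA recovers an indicator column and matches least squares", {
  withr::with_seed(4, {
    n <- 30
    y <- rep(c("a", "b"), each = n / 2)
    X <- cbind(as.numeric(y == "b"), matrix(rnorm(n * 4, sd = 0.3), n))
    fit <- pls_da_fit(X, y, A = 1)
    expect_equal(predict(fit, X)$predicted, y)

    # score vectors are mutually orthogonal
    fit3 <- pls_da_fit(matrix(rnorm(20 * 6), 20), rep(c("a", "b"), 10), A = 3)
    G <- crossprod(fit3$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)

    # with A = rank(X), fitted responses reproduce least squares
    X2 <- matrix(rnorm(20 * 5), 20)
    y2 <- rep(c("a", "b"), 10)
    fit_full <- pls_da_fit(X2, y2, A = 5)
    Y2 <- cbind(as.numeric(y2 == "a"), as.numeric(y2 == "b"))
    ls_fit <- stats::lm.fit(cbind(1, X2), Y2)
    pred_ls <- cbind(1, X2) %*% ls_fit$coefficients
    expect_equal(unname(predict(fit_full, X2, type = "scores")),
                 unname(pred_ls), tolerance = 1e-6)

    # duplicating every sample leaves the regression matrix unchanged
    fit_dup <- pls_da_fit(rbind(X2, X2), c(y2, y2), A = 3)
    fit_one <- pls_da_fit(X2, y2, A = 3)
    expect_equal(fit_dup$B, fit_one$B, tolerance = 1e-8)

    expect_warning(pls_da_fit(matrix(rnorm(12), 6, 2), rep(c("a", "b"), 3), A = 5),
                   "truncated")
  })
})

test_that("kernel matrices obey the closed forms", {
  X <- matrix(rnorm(12), 4)
  K <- rbf_kernel_matrix(X, gamma = 0.5)
  expect_equal(diag(K), rep(1, 4))
  expect_equal(K, t(K))
  expect_equal(unname(rbf_kernel_matrix(X, gamma = 0)[2, 3]), 1)

  # ||x - z||^2 = 1 and gamma = ln 2 gives exactly 1/2
  x1 <- matrix(c(0, 0), 1); x2 <- matrix(c(1, 0), 1)
  expect_equal(unname(rbf_kernel_matrix(x1, x2, gamma = log(2))[1, 1]), 0.5)

  expect_equal(unname(linear_kernel_matrix(x1, x2)[1, 1]), 0)
  expect_equal(linear_kernel_matrix(X), tcrossprod(X), ignore_attr = TRUE)
})

test_that("KPLS-DA with a linear kernel reproduces PLS-DA", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 30; d <- 6
      X <- matrix(rnorm(n * d), n)
      y <- sample(rep(c("a", "b"), n / 2))
      Xte <- matrix(rnorm(10 * d), 10)
      p1 <- predict(pls_da_fit(X, y, A = 2), Xte, type = "scores")
      kf <- kpls_da_fit(linear_kernel_matrix(X), y, A = 2)
      p2 <- predict(kf, linear_kernel_matrix(Xte, X), type = "scores")
      expect_equal(p1, p2, tolerance = 1e-6)
    })
  }

  # A = 1 on well-separated classes fits the training set
  blobs <- make_blob_datasets(7)
  Xtr <- concatenate_modalities(blobs$train)
  ytr <- blobs$train$meta$label
  kf <- kpls_da_fit(rbf_kernel_matrix(Xtr, gamma = 0.05), ytr, A = 1)
  pr <- predict(kf, rbf_kernel_matrix(Xtr, Xtr, gamma = 0.05))
  expect_equal(pr$predicted, ytr)

  # permuting training order permutes nothing observable at test time
  ord <- withr::with_seed(9, sample(nrow(Xtr)))
  kf2 <- kpls_da_fit(rbf_kernel_matrix(Xtr[ord, ], gamma = 0.05), ytr[ord], A = 1)
  pr2 <- predict(kf2, rbf_kernel_matrix(Xtr, Xtr[ord, ], gamma = 0.05))
  expect_equal(pr2$predicted, pr$predicted)

  expect_error(kpls_da_fit(matrix(rnorm(12), 3, 4), c("a", "b", "a")),
               "symmetric")
})

test_that("kernel fusion is a weighted average with L1-normalized weights", {
  K1 <- diag(2); K2 <- matrix(1, 2, 2)
  expect_equal(unclass(fuse_kernels(list(K1), fusion_weights(1))),
               K1, ignore_attr = TRUE)
  expect_equal(unclass(fuse_kernels(list(K2, K2), fusion_weights(c(0.5, 0.5)))),
               K2, ignore_attr = TRUE)
  f <- fuse_kernels(list(K1, K2), fusion_weights(c(0.5, 0.5)))
  expect_equal(unclass(f), matrix(c(1, 0.5, 0.5, 1), 2), ignore_attr = TRUE)

  w <- fusion_weights(c(2, 6))
  expect_equal(sum(abs(w)), 1)
  expect_error(fusion_weights(c(0.5, 0.2), normalize = FALSE), "sum")
  expect_error(fuse_kernels(list(K1, matrix(0, 3, 3)), fusion_weights(c(1, 1))),
               "shape")

  # PSD preservation under non-negative weights
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- matrix(rnorm(36), 6); B <- matrix(rnorm(36), 6)
      Ks <- list(crossprod(A), crossprod(B))
      a <- abs(rnorm(2)); a <- a / sum(a)
      ev <- eigen(fuse_kernels(Ks, fusion_weights(a, normalize = FALSE)),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    })
  }
})

test_that("the simplex grid enumerates L1-normalized candidates", {
  g <- simplex_grid(2, 0.1)
  expect_length(g, 11)
  expect_true(all(vapply(g, sum, 0) == 1))
  g3 <- simplex_grid(3, 0.25)
  expect_length(g3, 15) # compositions of 4 into 3 parts
  expect_true(all(vapply(g3, function(a) all(a >= 0), TRUE)))
  expect_error(simplex_grid(2, 0.3), "whole number")
})

test_that("fusion-weight tuning prefers the informative kernel", {
  wins <- 0
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40
      y <- rep(c("a", "b"), each = n / 2)
      X_info <- matrix(rnorm(n * 5), n) + 0.9 * as.numeric(y == "b")
      X_noise <- matrix(rnorm(n * 5), n)
      kernels <- list(info = rbf_kernel_matrix(X_info, gamma = 0.3),
                      noise = rbf_kernel_matrix(X_noise, gamma = 0.3))
      folds <- split(sample(seq_len(n)), rep(1:3, length.out = n))
      w <- tune_fusion_weights(kernels, y, folds, A = 1)
      if (w[1] > w[2]) wins <- wins + 1
    })
  }
  expect_gte(wins, 4)

  # single kernel short-circuits to weight 1
  w1 <- tune_fusion_weights(list(diag(4)), rep(c("a", "b"), 2), list(1:2, 3:4))
  expect_equal(as.numeric(w1), 1)
})

test_that("MBPLS-DA equals PLS-DA for one block and ignores zeroed blocks", {
  withr::with_seed(11, {
    n <- 24
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 6), n) + as.numeric(y == "b")
    noise <- matrix(rnorm(n * 4), n)

    mb1 <- mbpls_da_fit(list(X), y, A = 2, block_weights = 1)
    ref <- pls_da_fit(X, y, A = 2)
    expect_equal(predict(mb1, list(X), type = "scores"),
                 predict(ref, X, type = "scores"))

    # zero weight on the noise block reproduces the informative-only fit
    mb0 <- mbpls_da_fit(list(X, noise), y, A = 2, block_weights = c(1, 0))
    expect_equal(unname(predict(mb0, list(X, noise), type = "scores")),
                 unname(predict(ref, X, type = "scores")), tolerance = 1e-8)

    # permuting blocks together with their weights changes nothing
    mb_a <- mbpls_da_fit(list(X, noise), y, A = 2, block_weights = c(0.7, 0.3))
    mb_b <- mbpls_da_fit(list(noise, X), y, A = 2, block_weights = c(0.3, 0.7))
    expect_equal(predict(mb_a, list(X, noise), type = "scores"),
                 predict(mb_b, list(noise, X), type = "scores"),
                 tolerance = 1e-8)

    expect_error(mbpls_da_fit(list(X, noise[1:10, ]), y), "same number of rows")
  })
})
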