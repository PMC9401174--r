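test_that("LOPO builds one leak-free fold per patient", {
  ds <- simulate_dataset(quick_cfg(seed = 1, n_pat = 3, n_vox = 4))
  plan <- lopo_folds(ds)
  expect_equal(nrow(plan), 6)
  for (i in seq_len(nrow(plan))) {
    expect_length(intersect(plan$train_patients[[i]], plan$test_patients[[i]]), 0)
  }
  # every voxel tested exactly once
  expect_setequal(unlist(plan$test_voxels), ds$meta$voxel_id)
  expect_equal(sum(lengths(plan$test_voxels)), n_voxels(ds))

  # a class with a single patient breaks some training split
  tiny <- subset_voxels(ds, ds$meta$patient_id %in%
                          c("neg_p01", "pos_p01", "pos_p02"))
  expect_error(lopo_folds(tiny), "absent from the training split")
})

test_that("grouped k-fold stratifies patients and respects the seed", {
  ds <- simulate_dataset(quick_cfg(seed = 2, n_pat = 3, n_vox = 4))
  plan <- grouped_kfold(ds, k = 3, seed = 5)
  expect_equal(nrow(plan), 3)
  expect_equal(sort(lengths(plan$test_patients)), c(2, 2, 2))
  expect_setequal(unlist(plan$test_voxels), ds$meta$voxel_id)
  for (i in 1:3) {
    expect_length(intersect(plan$train_patients[[i]], plan$test_patients[[i]]), 0)
  }
  plan2 <- grouped_kfold(ds, k = 3, seed = 5)
  expect_identical(plan$test_patients, plan2$test_patients)
  expect_error(grouped_kfold(ds, k = 10), "exceeds")
})

test_that("naive voxel k-fold splits patients across folds", {
  ds <- simulate_dataset(quick_cfg(seed = 3, n_pat = 3, n_vox = 6))
  plan <- voxel_kfold(ds, k = 3, seed = 1)
  expect_setequal(unlist(plan$test_voxels), ds$meta$voxel_id)
  overlap <- purrr::map_lgl(seq_len(nrow(plan)), function(i) {
    length(intersect(plan$train_patients[[i]], plan$test_patients[[i]])) > 0
  })
  expect_true(any(overlap)) # the leakage this protocol demonstrates
})

test_that("MCC matches the closed form and its conventions", {
  expect_equal(mcc(c("a", "b", "a", "b"), c("a", "b", "a", "b")), 1)
  expect_equal(mcc(c("a", "b", "a", "b"), c("a", "a", "a", "a")), 0)
  # TP=3, FN=1, FP=1, TN=3 -> (9 - 1) / sqrt(4^4) = 0.5
  truth <- c(rep("pos", 4), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", "neg", "neg", "neg", "pos")
  expect_equal(mcc(truth, pred, positive = "pos"), 0.5)

  # symmetry: swapping both labelings preserves; flipping predictions negates
  withr::with_seed(5, {
    for (i in 1:20) {
      y <- sample(c("x", "y"), 12, replace = TRUE)
      p <- sample(c("x", "y"), 12, replace = TRUE)
      if (length(unique(y)) < 2) next
      swap <- function(v) ifelse(v == "x", "y", "x")
      expect_equal(mcc(y, p), mcc(swap(y), swap(p)))
      expect_equal(mcc(y, swap(p)), -mcc(y, p))
    }
  })
  expect_error(mcc(c("a", "b"), "a"), "equal length")
  expect_error(mcc(c("a", "b", "c"), c("a", "b", "c")), "binary")
})

test_that("ROC/AUC equals the Mann-Whitney probability with tie handling", {
  expect_equal(roc_auc(c("n", "n", "p", "p"), c(1, 2, 3, 4))$auc, 1)
  expect_equal(roc_auc(c("n", "n", "p", "p"), c(1, 1, 1, 1))$auc, 0.5)
  r <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), positive = "1")
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)

  # cross-check against pROC on random problems
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(10:40, 1)
      y <- sample(c("a", "b"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- rnorm(n) + (y == "b")
      expect_equal(roc_auc(y, s, positive = "b")$auc,
                   as.numeric(pROC::auc(pROC::roc(y, s, levels = c("a", "b"),
                                                  direction = "<", quiet = TRUE))),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(rep("a", 5), rnorm(5)), "single-class")
})

test_that("DeLong test agrees with the naive structural components and pROC", {
  withr::with_seed(12, {
    y <- rep(c("a", "b"), each = 10)
    s1 <- rnorm(20) + (y == "b")
    s2 <- s1 * 0.5 + rnorm(20, sd = 0.5)
    res <- delong_test(s1, s2, y)
    oracle <- delong_naive(s1, s2, y, positive = "b")
    expect_equal(res$delta_auc, oracle$delta, tolerance = 1e-10)
    expect_equal(res$variance, oracle$variance, tolerance = 1e-10)

    skip_if_not_installed("pROC")
    pr <- pROC::roc.test(
      pROC::roc(y, s1, levels = c("a", "b"), direction = "<", quiet = TRUE),
      pROC::roc(y, s2, levels = c("a", "b"), direction = "<", quiet = TRUE),
      method = "delong"
    )
    expect_equal(res$p_value, pr$p.value, tolerance = 1e-9)
  })

  res_id <- delong_test(1:10, 1:10, rep(c("a", "b"), 5))
  expect_equal(res_id$delta_auc, 0)
  expect_equal(res_id$p_value, 1)
})

test_that("random grid search selects by inner MCC with documented tie-breaks", {
  ds <- simulate_dataset(quick_cfg(seed = 6, n_pat = 4, n_vox = 4, effect = 2,
                                   patient_sd = 0.05))
  method <- method_slcnn(slcnn_config(K_spec = 2, N_spec = 8, stride_s = 4,
                                      epochs = 20, eta = 0.1, batch_size = 8))
  # single-candidate grid short-circuits
  res1 <- rgs_search(method, ds, list(eta = 0.1), seed = 1)
  expect_equal(res1$params, list(eta = 0.1))
  expect_equal(nrow(res1$results), 0)
  expect_setequal(res1$patients_seen, patient_ids(ds))

  # the returned candidate attains the maximal inner MCC
  res <- rgs_search(method, ds, list(eta = c(0.05, 0.1), K_spec = c(2, 3)),
                    n_draws = 4, seed = 2)
  expect_gte(res$inner_mcc, max(res$results$inner_mcc) - 1e-12)
  # ties broken toward smaller models, then draw order
  tied <- res$results[res$results$inner_mcc == max(res$results$inner_mcc), ]
  chosen_complexity <- method$complexity(res$params)
  expect_equal(chosen_complexity, min(tied$complexity))
})

test_that("nested CV pools one prediction per voxel and never leaks", {
  ds <- simulate_dataset(quick_cfg(seed = 4, n_pat = 4, n_vox = 4, effect = 2.2,
                                   patient_sd = 0.05))
  method <- method_slcnn(slcnn_config(K_spec = 2, N_spec = 8, stride_s = 4,
                                      epochs = 30, eta = 0.1, batch_size = 8))
  cv <- nested_cv(method, ds, protocol = "lopo", repetitions = 2, seed = 3)
  counts <- dplyr::count(cv$predictions, .data$rep, .data$voxel_id)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(cv$predictions), 2 * n_voxels(ds))
  expect_true(cv$leakage_ok)
  expect_true(all(cv$mcc >= -1 & cv$mcc <= 1))

  # deterministic: same call, same pooled predictions
  cv2 <- nested_cv(method, ds, protocol = "lopo", repetitions = 2, seed = 3)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$mcc, cv2$mcc)

  # strong signal is recovered out of fold
  expect_gt(cv$mcc_mean, 0.8)

  # baseline methods run through the same harness
  for (mth in list(method_svm_rbf(C = 1), method_pls_da(A = 2),
                   method_kpls_da(gamma = 0.05, A = 2), method_mbpls_da(A = 2))) {
    cvb <- nested_cv(mth, ds, protocol = "kfold3", seed = 1)
    expect_equal(nrow(cvb$predictions), n_voxels(ds))
    expect_gt(cvb$mcc_mean, 0.5)
  }

  # glance/tidy expose the summary surface
  g <- glance(cv)
  expect_equal(g$repetitions, 2)
  expect_named(tidy(cv), names(cv$predictions))
})
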