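#' RBF-kernel SVM on concatenated modalities
#'
#' Chemometric reference classifier: images and spectra of each voxel are
#' concatenated into a unique sample and fed to a soft-margin SVM with
#' radial basis kernel (delegated to \pkg{e1071}).
#'
#' @param train,test `mrsi_dataset` objects with identical modality shapes.
#' @param C Regularization parameter (> 0).
#' @param gamma RBF width parameter (> 0); default `1 / n_features`.
#' @param modalities Which streams to concatenate (see
#'   [concatenate_modalities()]).
#' @return A tibble with `voxel_id`, `patient_id`, `truth`, `predicted` and
#'   one `score_<class>` column per class (signed decision values for
#'   binary tasks).
#' @export
svm_rbf_classify <- function(train, test, C = 1, gamma = NULL,
                             modalities = "all") {
  if (C <= 0) abort("C must be positive")
  Xtr <- concatenate_modalities(train, modalities)
  Xte <- concatenate_modalities(test, modalities)
  y <- factor(train$meta$label, levels = train$label_levels)
  y <- droplevels(y)
  if (nlevels(y) < 2) abort("training set contains a single class")
  if (is.null(gamma)) gamma <- 1 / ncol(Xtr)
  if (gamma <= 0) abort("gamma must be positive")
  fit <- e1071::svm(Xtr, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  pr <- predict(fit, Xte, decision.values = TRUE)
  out <- tibble::tibble(
    voxel_id = test$meta$voxel_id,
    patient_id = test$meta$patient_id,
    truth = test$meta$label,
    predicted = as.character(pr)
  )
  dv <- attr(pr, "decision.values")
  if (nlevels(y) == 2) {
    # orient the decision value toward the second (positive) class
    lv <- levels(y)
    pair <- colnames(dv)[1]
    s <- as.numeric(dv[, 1])
    if (identical(pair, paste(lv[1], lv[2], sep = "/"))) s <- -s
    out[[paste0("score_", lv[1])]] <- -s
    out[[paste0("score_", lv[2])]] <- s
  } else {
    for (lv in levels(y)) {
      out[[paste0("score_", lv)]] <- as.numeric(as.character(pr) == lv)
    }
  }
  out
}

# ---- PLS-DA (NIPALS PLS2 with one-hot response) -----------------------------

one_hot <- function(y) {
  Y <- matrix(0, length(y), nlevels(y))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  colnames(Y) <- levels(y)
  Y
}

#' Fit partial least squares discriminant analysis
#'
#' NIPALS PLS2 on column-centered predictors against a one-hot class
#' coding; prediction decodes the fitted response by arg-max. Latent score
#' vectors are mutually orthogonal; if the requested number of components
#' exceeds the predictor rank the fit is truncated with a warning.
#'
#' @param X Numeric matrix `n x d`.
#' @param labels Class labels, length `n`.
#' @param A Number of latent components (>= 1).
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return An object of class `pls_da` with weights `W`, loadings `P`,
#'   response loadings `Q`, scores `T`, regression matrix `B` and the
#'   centering vectors.
#' @export
pls_da_fit <- function(X, labels, A = 2L, max_iter = 500L, tol = 1e-10) {
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) < 2) abort("labels must contain at least two classes")
  if (A < 1) abort("A must be >= 1")
  X <- as.matrix(X)
  Y <- one_hot(y)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  n <- nrow(X); d <- ncol(X); m <- ncol(Y)
  A_req <- as.integer(A)
  A_max <- min(n - 1L, d)
  Wm <- matrix(0, d, A_req); Pm <- matrix(0, d, A_req)
  Qm <- matrix(0, m, A_req); Tm <- matrix(0, n, A_req)
  a_done <- 0L
  for (a in seq_len(A_req)) {
    if (a > A_max || sum(Xc^2) < tol) break
    u <- Yc[, which.max(colSums(Yc^2))]
    w_old <- rep(0, d)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_vec <- drop(Xc %*% w)
      tt <- sum(t_vec^2)
      q <- drop(crossprod(Yc, t_vec)) / tt
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    t_vec <- drop(Xc %*% w)
    tt <- sum(t_vec^2)
    if (tt < tol) break
    p <- drop(crossprod(Xc, t_vec)) / tt
    q <- drop(crossprod(Yc, t_vec)) / tt
    Wm[, a] <- w; Pm[, a] <- p; Qm[, a] <- q; Tm[, a] <- t_vec
    Xc <- Xc - tcrossprod(t_vec, p)
    Yc <- Yc - tcrossprod(t_vec, q)
    a_done <- a
  }
  if (a_done < A_req) {
    warn(sprintf("PLS-DA truncated to %d component(s) (predictor rank)", a_done))
    Wm <- Wm[, seq_len(a_done), drop = FALSE]
    Pm <- Pm[, seq_len(a_done), drop = FALSE]
    Qm <- Qm[, seq_len(a_done), drop = FALSE]
    Tm <- Tm[, seq_len(a_done), drop = FALSE]
  }
  B <- Wm %*% solve(crossprod(Pm, Wm), t(Qm))
  structure(
    list(W = Wm, P = Pm, Q = Qm, T = Tm, B = B, x_mean = x_mean,
         y_mean = y_mean, levels = levels(y), A = a_done),
    class = "pls_da"
  )
}

#' Predict from a PLS-DA fit
#'
#' @param object A `pls_da` model.
#' @param newdata Numeric matrix with the training column layout.
#' @param type `"tibble"` (predicted class plus `score_<class>` fitted
#'   responses) or `"scores"` for the raw fitted response matrix.
#' @param ... Unused.
#' @return Tibble or matrix of continuous class scores.
#' @export
predict.pls_da <- function(object, newdata, type = c("tibble", "scores"), ...) {
  type <- match.arg(type)
  Yhat <- sweep(as.matrix(newdata), 2, object$x_mean) %*% object$B
  Yhat <- sweep(Yhat, 2, object$y_mean, "+")
  colnames(Yhat) <- object$levels
  if (type == "scores") return(Yhat)
  pred <- object$levels[max.col(Yhat, ties.method = "first")]
  scores <- tibble::as_tibble(Yhat, .name_repair = "minimal")
  names(scores) <- paste0("score_", object$levels)
  dplyr::bind_cols(tibble::tibble(predicted = pred), scores)
}

#' @exportS3Method tidy pls_da
#' @describeIn pls_da_fit One row per latent component: explained predictor
#'   variance of the score vector.
#' @param x A `pls_da` model.
#' @param ... Unused.
#' @export
tidy.pls_da <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$A),
    score_variance = apply(x$T, 2, function(t) sum(t^2))
  )
}

#' @exportS3Method glance pls_da
#' @describeIn pls_da_fit One-row fit summary.
#' @export
glance.pls_da <- function(x, ...) {
  tibble::tibble(n_components = x$A, n_classes = length(x$levels))
}

# ---- kernels ----------------------------------------------------------------

#' Radial basis function kernel matrix
#'
#' `K(x, z) = exp(-gamma * ||x - z||^2)`. With one argument the Gram matrix
#' is symmetric with unit diagonal.
#'
#' @param X1 Numeric matrix `n1 x d`.
#' @param X2 Optional second matrix `n2 x d`; default `X1`.
#' @param gamma Positive width parameter (`gamma = 0` is allowed and gives
#'   the all-ones matrix).
#' @return `n1 x n2` kernel matrix with attributes `kernel = "rbf"` and
#'   `gamma`.
#' @export
rbf_kernel_matrix <- function(X1, X2 = NULL, gamma = 1) {
  if (gamma < 0) abort("gamma must be non-negative")
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  attr(K, "kernel") <- "rbf"
  attr(K, "gamma") <- gamma
  K
}

#' Linear kernel matrix
#'
#' @inheritParams rbf_kernel_matrix
#' @return `n1 x n2` inner-product matrix with attribute
#'   `kernel = "linear"`.
#' @export
linear_kernel_matrix <- function(X1, X2 = NULL) {
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  K <- tcrossprod(X1, X2)
  attr(K, "kernel") <- "linear"
  K
}

# ---- kernel PLS-DA ----------------------------------------------------------

#' Fit kernel PLS discriminant analysis
#'
#' Dual-form PLS on a double-centered Gram matrix against the one-hot class
#' coding; the kernel-space analogue of [pls_da_fit()]. With a linear
#' kernel the predictions reproduce PLS-DA.
#'
#' @param K Symmetric `n x n` training Gram matrix (uncentered; centering
#'   is applied internally and test rows are centered consistently).
#' @param labels Class labels, length `n`.
#' @param A Number of latent components.
#' @param max_iter,tol Inner-loop controls.
#' @return An object of class `kpls_da` holding dual coefficients and
#'   centering information.
#' @export
kpls_da_fit <- function(K, labels, A = 2L, max_iter = 500L, tol = 1e-10) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n || max(abs(K - t(K))) > 1e-8) {
    abort("K must be a symmetric square matrix")
  }
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) < 2) abort("labels must contain at least two classes")
  Y <- one_hot(y)
  y_mean <- colMeans(Y)
  Y0 <- sweep(Y, 2, y_mean)
  H <- diag(n) - matrix(1 / n, n, n)
  K0 <- H %*% K %*% H
  Kc <- K0
  Yc <- Y0
  A_req <- as.integer(A)
  Tm <- matrix(0, n, A_req); Um <- matrix(0, n, A_req)
  a_done <- 0L
  for (a in seq_len(A_req)) {
    if (sum(Kc^2) < tol) break
    u <- Yc[, which.max(colSums(Yc^2))]
    if (sum(u^2) < tol) break
    u <- u / sqrt(sum(u^2))
    u_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      t_vec <- drop(Kc %*% u)
      nt <- sqrt(sum(t_vec^2))
      if (nt < tol) break
      t_vec <- t_vec / nt
      cvec <- drop(crossprod(Yc, t_vec))
      u <- drop(Yc %*% cvec)
      u <- u / sqrt(sum(u^2))
      if (sum((u - u_old)^2) < tol) break
      u_old <- u
    }
    t_vec <- drop(Kc %*% u)
    nt <- sqrt(sum(t_vec^2))
    if (nt < tol) break
    t_vec <- t_vec / nt
    Tm[, a] <- t_vec; Um[, a] <- u
    D <- diag(n) - tcrossprod(t_vec)
    Kc <- D %*% Kc %*% D
    Yc <- Yc - tcrossprod(t_vec) %*% Yc
    a_done <- a
  }
  if (a_done < 1) abort("kernel PLS failed: degenerate kernel or response")
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  Um <- Um[, seq_len(a_done), drop = FALSE]
  if (a_done < A_req) {
    warn(sprintf("KPLS-DA truncated to %d component(s)", a_done))
  }
  Bd <- Um %*% solve(crossprod(Tm, K0 %*% Um), crossprod(Tm, Y0))
  structure(
    list(B_dual = Bd, y_mean = y_mean, levels = levels(y), A = a_done,
         n_train = n, K_colsums = colSums(K)),
    class = "kpls_da"
  )
}

#' Predict from a kernel PLS-DA fit
#'
#' @param object A `kpls_da` model.
#' @param K_test `n_test x n_train` cross-kernel between test and training
#'   samples (uncentered; the training feature-space centering is applied).
#' @param type `"tibble"` or `"scores"`.
#' @param ... Unused.
#' @return Tibble or matrix of continuous class scores.
#' @export
predict.kpls_da <- function(object, K_test, type = c("tibble", "scores"), ...) {
  type <- match.arg(type)
  K_test <- as.matrix(K_test)
  n <- object$n_train
  if (ncol(K_test) != n) abort("K_test must have one column per training sample")
  H <- diag(n) - matrix(1 / n, n, n)
  Ktc <- (K_test - matrix(object$K_colsums / n, nrow(K_test), n, byrow = TRUE)) %*% H
  Yhat <- Ktc %*% object$B_dual
  Yhat <- sweep(Yhat, 2, object$y_mean, "+")
  colnames(Yhat) <- object$levels
  if (type == "scores") return(Yhat)
  pred <- object$levels[max.col(Yhat, ties.method = "first")]
  scores <- tibble::as_tibble(Yhat, .name_repair = "minimal")
  names(scores) <- paste0("score_", object$levels)
  dplyr::bind_cols(tibble::tibble(predicted = pred), scores)
}

# ---- multi-kernel fusion ----------------------------------------------------

#' L1-normalized kernel fusion weights
#'
#' @param a Numeric weight vector.
#' @param normalize Divide by `sum(abs(a))` (default `TRUE`); with
#'   `FALSE` the vector must already satisfy the constraint.
#' @return A `fusion_weights` vector with `sum(abs(a)) == 1` within 1e-10.
#' @export
fusion_weights <- function(a, normalize = TRUE) {
  a <- as.numeric(a)
  s <- sum(abs(a))
  if (s == 0) abort("fusion weights cannot be all zero")
  if (normalize) a <- a / s
  if (abs(sum(abs(a)) - 1) > 1e-10) {
    abort("fusion weights must satisfy sum(|a_i|) = 1")
  }
  structure(a, class = "fusion_weights")
}

#' Weighted average of Gram matrices
#'
#' Multi-kernel fusion `K = sum_i a_i K_i` with L1-normalized weights: each
#' modality's kernel is computed and tuned independently, then merged into
#' a unique kernel.
#'
#' @param kernels List of `n x n` kernel matrices of equal shape.
#' @param weights A [fusion_weights()] vector (length `M`).
#' @return The fused kernel matrix (positive semi-definite whenever all
#'   components are PSD and all weights non-negative).
#' @export
fuse_kernels <- function(kernels, weights) {
  if (!inherits(weights, "fusion_weights")) weights <- fusion_weights(weights)
  if (length(kernels) != length(weights)) {
    abort("need exactly one weight per kernel")
  }
  dims <- purrr::map(kernels, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    abort("all kernels must share one shape")
  }
  out <- matrix(0, nrow(kernels[[1]]), ncol(kernels[[1]]))
  for (i in seq_along(kernels)) out <- out + weights[i] * kernels[[i]]
  attr(out, "kernel") <- "fused"
  attr(out, "weights") <- as.numeric(weights)
  out
}

#' Candidate grid on the weight simplex
#'
#' All non-negative weight vectors of length `M` with entries on a grid of
#' resolution `step` that sum exactly to 1.
#'
#' @param M Number of kernels.
#' @param step Grid resolution (1/step must be a whole number).
#' @return List of numeric weight vectors, in lexicographic order.
#' @export
simplex_grid <- function(M, step = 0.1) {
  units <- round(1 / step)
  if (abs(units - 1 / step) > 1e-8) abort("1/step must be a whole number")
  rec <- function(m, left) {
    if (m == 1) return(list(left))
    out <- list()
    for (k in 0:left) {
      for (rest in rec(m - 1, left - k)) {
        out[[length(out) + 1L]] <- c(k, rest)
      }
    }
    out
  }
  purrr::map(rec(M, units), ~ .x / units)
}

#' Tune fusion weights by inner cross-validated MCC
#'
#' Evaluates every candidate weight vector by the pooled Matthews
#' correlation of KPLS-DA on the fused kernel over the supplied inner
#' folds; returns the best candidate (ties broken by grid order).
#'
#' @param kernels List of `n x n` kernel matrices (one per modality/view).
#' @param labels Class labels, length `n` (binary).
#' @param folds List of test-index vectors partitioning `1:n` (build them
#'   patient-grouped to avoid leakage).
#' @param grid List of candidate weight vectors; defaults to
#'   [simplex_grid()] with step 0.1.
#' @param A Number of KPLS components used in the evaluation.
#' @return The winning [fusion_weights()], with attributes `mcc` (its inner
#'   score) and `scores` (all candidates').
#' @export
tune_fusion_weights <- function(kernels, labels, folds, grid = NULL, A = 2L) {
  M <- length(kernels)
  if (M < 1) abort("need at least one kernel")
  if (M == 1) {
    return(structure(fusion_weights(1), mcc = NA_real_, scores = NA_real_))
  }
  if (is.null(grid)) grid <- simplex_grid(M, 0.1)
  if (length(grid) == 0) abort("candidate grid is empty")
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  scores <- purrr::map_dbl(grid, function(a) {
    Kf <- fuse_kernels(kernels, fusion_weights(a, normalize = FALSE))
    preds <- character(length(y))
    for (test_idx in folds) {
      tr <- setdiff(seq_along(y), test_idx)
      fit <- tryCatch(
        kpls_da_fit(Kf[tr, tr, drop = FALSE], y[tr], A = A),
        error = function(e) NULL
      )
      if (is.null(fit)) return(-Inf)
      pr <- predict(fit, Kf[test_idx, tr, drop = FALSE], type = "scores")
      preds[test_idx] <- fit$levels[max.col(pr, ties.method = "first")]
    }
    mcc(as.character(y), preds)
  })
  best <- which.max(scores) # which.max takes the first maximum: grid-order tie-break
  structure(fusion_weights(grid[[best]], normalize = FALSE),
            mcc = scores[best], scores = scores)
}

# ---- multi-block PLS-DA -----------------------------------------------------

#' Fit multi-block PLS discriminant analysis
#'
#' Each data block (type/view) is scaled by its block weight and the
#' weighted blocks are concatenated before a PLS-DA fit, letting the model
#' penalize or favor less informative data types. With a single block and
#' weight 1 this is exactly PLS-DA.
#'
#' @param blocks List of numeric matrices sharing `n` rows.
#' @param labels Class labels, length `n`.
#' @param A Number of latent components.
#' @param block_weights Numeric vector, one non-negative weight per block
#'   (default equal weights summing to 1).
#' @return An object of class `mbpls_da` wrapping the inner `pls_da` fit
#'   and the block structure.
#' @export
mbpls_da_fit <- function(blocks, labels, A = 2L, block_weights = NULL) {
  if (length(blocks) < 1) abort("need at least one block")
  ns <- unique(purrr::map_int(blocks, nrow))
  if (length(ns) != 1) abort("all blocks must share the same number of rows")
  M <- length(blocks)
  if (is.null(block_weights)) block_weights <- rep(1 / M, M)
  if (length(block_weights) != M) abort("need one weight per block")
  if (any(block_weights < 0)) abort("block weights must be non-negative")
  Xw <- do.call(cbind, purrr::map2(blocks, block_weights, function(b, w) b * w))
  fit <- pls_da_fit(Xw, labels, A = A)
  structure(
    list(fit = fit, block_weights = block_weights,
         block_cols = purrr::map_int(blocks, ncol), levels = fit$levels),
    class = "mbpls_da"
  )
}

#' Predict from a multi-block PLS-DA fit
#'
#' @param object An `mbpls_da` model.
#' @param blocks List of matrices with the training block layout.
#' @param type `"tibble"` or `"scores"`.
#' @param ... Unused.
#' @return Tibble or matrix of continuous class scores.
#' @export
predict.mbpls_da <- function(object, blocks, type = c("tibble", "scores"), ...) {
  if (!identical(purrr::map_int(blocks, ncol), object$block_cols)) {
    abort("block column layout does not match the fit")
  }
  Xw <- do.call(cbind, purrr::map2(blocks, object$block_weights,
                                   function(b, w) b * w))
  predict(object$fit, Xw, type = match.arg(type))
}
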