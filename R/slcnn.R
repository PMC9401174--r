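#' Hyper-parameters of the single-layer CNN
#'
#' The network has one convolutional hidden layer per modality branch: a 1D
#' branch sliding `K_spec` kernels of size `N_spec` at stride `stride_s`
#' over the spectrum (channels summed inside each kernel), and optionally a
#' 2D branch (`K_img` kernels of side `N_img`, stride 1, followed by
#' non-overlapping max pooling of side `pool_size`) over the stacked image
#' contrasts. Branch outputs are flattened, merged, and fed to a softmax
#' output layer.
#'
#' @param K_spec Number of spectral kernels.
#' @param N_spec Spectral kernel size N (bins); the receptive-field width.
#' @param stride_s Convolution stride s (>= 1).
#' @param K_img Number of image kernels; 0 disables the image branch.
#' @param N_img Image kernel side.
#' @param pool_size Max-pooling window side (non-overlapping; ragged edges
#'   truncated).
#' @param eta Learning rate of plain mini-batch gradient descent.
#' @param lambda1 Weight-decay strength: `lambda1 * sum(weights^2)` over all
#'   convolutional and output weights (biases excluded).
#' @param lambda2 Smoothness strength: `lambda2` times the sum of squared
#'   first differences of adjacent weights within each kernel (both axes for
#'   2D kernels) — the penalty against large variations between neighboring
#'   kernel weights.
#' @param epochs Training epochs (no early stopping; model selection happens
#'   in the nested CV).
#' @param batch_size Mini-batch size.
#' @param class_weighting Use inverse-class-frequency weights in the
#'   cross-entropy (default `TRUE`; the mechanism for class-unbalanced
#'   cohorts).
#' @param seed Seed for initialization and batch shuffling; training is a
#'   pure function of (data, config).
#' @return An object of class `slcnn_config`.
#' @export
slcnn_config <- function(K_spec = 4L, N_spec = 32L, stride_s = 4L,
                         K_img = 0L, N_img = 3L, pool_size = 2L,
                         eta = 0.05, lambda1 = 1e-4, lambda2 = 1e-3,
                         epochs = 100L, batch_size = 32L,
                         class_weighting = TRUE, seed = 1L) {
  if (stride_s < 1) abort("stride_s must be >= 1")
  if (eta <= 0) abort("eta must be positive")
  if (lambda1 < 0 || lambda2 < 0) abort("regularization strengths must be >= 0")
  structure(
    list(K_spec = as.integer(K_spec), N_spec = as.integer(N_spec),
         stride_s = as.integer(stride_s), K_img = as.integer(K_img),
         N_img = as.integer(N_img), pool_size = as.integer(pool_size),
         eta = eta, lambda1 = lambda1, lambda2 = lambda2,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         class_weighting = isTRUE(class_weighting), seed = as.integer(seed)),
    class = "slcnn_config"
  )
}

#' Output length of a valid strided convolution
#'
#' @param P Input length in bins.
#' @param N Kernel size (1 <= N <= P).
#' @param s Stride (>= 1).
#' @return `floor((P - N) / s) + 1`, the number of kernel positions.
#' @examples
#' conv_output_length(10, 3, 2) # positions start at bins 0, 2, 4, 6
#' @export
conv_output_length <- function(P, N, s = 1L) {
  if (N > P) abort("kernel size N must not exceed input length P")
  if (N < 1 || s < 1) abort("N and s must be >= 1")
  as.integer((P - N) %/% s + 1L)
}

# ---- internal geometry ------------------------------------------------------

slcnn_dims <- function(config, C, P, contrasts = character(), H = NULL, W = NULL) {
  Fs <- conv_output_length(P, config$N_spec, config$stride_s)
  dims <- list(C = C, P = P, F_spec = Fs, d_spec = config$K_spec * Fs,
               contrasts = contrasts)
  use_img <- config$K_img > 0 && length(contrasts) > 0
  dims$use_img <- use_img
  if (use_img) {
    if (config$N_img > min(H, W)) abort("N_img must not exceed the patch side")
    Hc <- H - config$N_img + 1L
    Wc <- W - config$N_img + 1L
    Ph <- Hc %/% config$pool_size
    Pw <- Wc %/% config$pool_size
    if (Ph < 1 || Pw < 1) abort("pool_size too large for the convolution output")
    dims <- c(dims, list(H = H, W = W, Cg = length(contrasts),
                         Hc = Hc, Wc = Wc, Ph = Ph, Pw = Pw,
                         F_img = Hc * Wc, d_img = config$K_img * Ph * Pw))
  } else {
    dims$d_img <- 0L
  }
  dims$d <- dims$d_spec + dims$d_img
  dims
}

# im2col for the 1D branch: rows ordered (sample-major) (r-1)*F + j
spec_design <- function(spectra_flat, C, P, N, s, F_spec) {
  n <- nrow(spectra_flat)
  cols_idx <- matrix(0L, nrow = C * N, ncol = F_spec)
  for (j in seq_len(F_spec)) {
    start <- (j - 1L) * s
    for (ch in seq_len(C)) {
      cols_idx[(ch - 1L) * N + seq_len(N), j] <- (ch - 1L) * P + start + seq_len(N)
    }
  }
  big <- spectra_flat[, as.vector(cols_idx), drop = FALSE]
  Z <- matrix(aperm(array(big, c(n, C * N, F_spec)), c(3, 1, 2)), nrow = n * F_spec)
  Z
}

# im2col for the 2D branch: conv positions row-major pos = (u-1)*Wc + v
img_design <- function(images_flat, Cg, H, W, N, Hc, Wc) {
  n <- nrow(images_flat)
  F_img <- Hc * Wc
  cols_idx <- matrix(0L, nrow = Cg * N * N, ncol = F_img)
  for (u in seq_len(Hc)) {
    for (v in seq_len(Wc)) {
      pos <- (u - 1L) * Wc + v
      for (g in seq_len(Cg)) {
        for (b in seq_len(N)) {
          rows_in_patch <- (g - 1L) * H * W + (v + b - 2L) * H + (u - 1L) + seq_len(N)
          cols_idx[(g - 1L) * N * N + (b - 1L) * N + seq_len(N), pos] <- rows_in_patch
        }
      }
    }
  }
  big <- images_flat[, as.vector(cols_idx), drop = FALSE]
  matrix(aperm(array(big, c(n, Cg * N * N, F_img)), c(3, 1, 2)), nrow = n * F_img)
}

# flattened per-voxel arrays + window designs for a dataset
slcnn_design <- function(ds, config, dims) {
  Xs <- concatenate_modalities(ds, "spectra")
  Zs <- spec_design(Xs, dims$C, dims$P, config$N_spec, config$stride_s, dims$F_spec)
  Zi <- NULL
  if (isTRUE(dims$use_img)) {
    Xi <- concatenate_modalities(ds, "images")
    Zi <- img_design(Xi, dims$Cg, dims$H, dims$W, config$N_img, dims$Hc, dims$Wc)
  }
  list(Zs = Zs, Zi = Zi, n = n_voxels(ds))
}

# pooled-cell membership: list of conv-position index vectors, cells row-major
pool_cells <- function(Hc, Wc, Ph, Pw, p) {
  cells <- vector("list", Ph * Pw)
  for (pu in seq_len(Ph)) {
    for (pv in seq_len(Pw)) {
      rows <- (pu - 1L) * p + seq_len(p)
      colsv <- (pv - 1L) * p + seq_len(p)
      pos <- as.vector(t(outer(rows - 1L, colsv, function(u0, v) u0 * Wc + v)))
      cells[[(pu - 1L) * Pw + pv]] <- pos
    }
  }
  cells
}

# forward pass on a design; returns merged features and backprop caches
slcnn_forward <- function(model, design) {
  cfg <- model$config
  dims <- model$dims
  n <- design$n
  Fs <- dims$F_spec
  A_s <- design$Zs %*% t(model$W_spec)
  A_s <- sweep(A_s, 2, model$b_spec, "+")
  H_s <- A_s * (A_s > 0)
  # reshape (F, n, K) -> n x (K * F) with column (k-1)*F + j
  Phi_s <- matrix(aperm(array(H_s, c(Fs, n, cfg$K_spec)), c(2, 1, 3)), nrow = n)
  cache <- list(A_s = A_s)
  if (isTRUE(dims$use_img)) {
    Fi <- dims$F_img
    A_i <- design$Zi %*% t(model$W_img)
    A_i <- sweep(A_i, 2, model$b_img, "+")
    H_i <- A_i * (A_i > 0)
    arr <- array(H_i, c(Fi, n, cfg$K_img))
    cells <- pool_cells(dims$Hc, dims$Wc, dims$Ph, dims$Pw, cfg$pool_size)
    n_cells <- length(cells)
    pooled <- array(0, c(n, cfg$K_img, n_cells))
    argmax <- array(1L, c(n, cfg$K_img, n_cells))
    for (ci in seq_along(cells)) {
      S <- cells[[ci]]
      m <- arr[S[1], , , drop = FALSE][1, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = n)
      am <- matrix(1L, n, cfg$K_img)
      for (si in seq_along(S)[-1]) {
        cand <- arr[S[si], , , drop = FALSE][1, , , drop = TRUE]
        if (is.null(dim(cand))) cand <- matrix(cand, nrow = n)
        upd <- cand > m
        m[upd] <- cand[upd]
        am[upd] <- si
      }
      pooled[, , ci] <- m
      argmax[, , ci] <- am
    }
    # flatten: column (k-1)*Ph*Pw + cell
    Phi_i <- matrix(aperm(pooled, c(1, 3, 2)), nrow = n)
    cache <- c(cache, list(A_i = A_i, argmax = argmax, cells = cells))
    Phi <- cbind(Phi_s, Phi_i)
  } else {
    Phi <- Phi_s
  }
  logits <- Phi %*% model$V
  logits <- sweep(logits, 2, model$b_out, "+")
  list(Phi = Phi, logits = logits, cache = cache)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- penalties --------------------------------------------------------------

smooth_1d_value <- function(Wmat, C, N) {
  tot <- 0
  for (k in seq_len(nrow(Wmat))) {
    for (ch in seq_len(C)) {
      w <- Wmat[k, (ch - 1L) * N + seq_len(N)]
      if (N > 1) tot <- tot + sum(diff(w)^2)
    }
  }
  tot
}

smooth_1d_grad <- function(Wmat, C, N) {
  G <- matrix(0, nrow(Wmat), ncol(Wmat))
  for (k in seq_len(nrow(Wmat))) {
    for (ch in seq_len(C)) {
      idx <- (ch - 1L) * N + seq_len(N)
      w <- Wmat[k, idx]
      if (N > 1) {
        d <- diff(w)
        g <- numeric(N)
        g[seq_len(N - 1)] <- g[seq_len(N - 1)] - 2 * d
        g[1 + seq_len(N - 1)] <- g[1 + seq_len(N - 1)] + 2 * d
        G[k, idx] <- g
      }
    }
  }
  G
}

smooth_2d_value <- function(Wmat, Cg, N) {
  tot <- 0
  for (k in seq_len(nrow(Wmat))) {
    for (g in seq_len(Cg)) {
      M <- matrix(Wmat[k, (g - 1L) * N * N + seq_len(N * N)], N, N)
      if (N > 1) {
        tot <- tot + sum((M[, -1, drop = FALSE] - M[, -N, drop = FALSE])^2)
        tot <- tot + sum((M[-1, , drop = FALSE] - M[-N, , drop = FALSE])^2)
      }
    }
  }
  tot
}

smooth_2d_grad <- function(Wmat, Cg, N) {
  G <- matrix(0, nrow(Wmat), ncol(Wmat))
  for (k in seq_len(nrow(Wmat))) {
    for (g in seq_len(Cg)) {
      idx <- (g - 1L) * N * N + seq_len(N * N)
      M <- matrix(Wmat[k, idx], N, N)
      Gm <- matrix(0, N, N)
      if (N > 1) {
        dh <- M[, -1, drop = FALSE] - M[, -N, drop = FALSE]
        Gm[, -N] <- Gm[, -N, drop = FALSE] - 2 * dh
        Gm[, -1] <- Gm[, -1, drop = FALSE] + 2 * dh
        dv <- M[-1, , drop = FALSE] - M[-N, , drop = FALSE]
        Gm[-N, ] <- Gm[-N, , drop = FALSE] - 2 * dv
        Gm[-1, ] <- Gm[-1, , drop = FALSE] + 2 * dv
      }
      G[k, idx] <- as.vector(Gm)
    }
  }
  G
}

#' Neighbor-variation smoothness penalty of the convolutional kernels
#'
#' Sum over kernels, channels and adjacent weight pairs of
#' `(w[i+1] - w[i])^2`; for 2D kernels the sum runs over horizontally and
#' vertically adjacent pairs. The output layer and all biases are excluded.
#' A constant kernel has penalty 0; any non-constant kernel has a strictly
#' positive penalty, and adding a constant to a kernel leaves it unchanged.
#'
#' @param model A trained or hand-built `slcnn`, or a plain numeric matrix
#'   of single-channel 1D kernels (one kernel per row) for quick checks.
#' @return Non-negative scalar.
#' @examples
#' smoothness_penalty(matrix(c(0, 1, 0), nrow = 1)) # (1-0)^2 + (0-1)^2 = 2
#' @export
smoothness_penalty <- function(model) {
  if (is.matrix(model)) {
    return(smooth_1d_value(model, 1L, ncol(model)))
  }
  stopifnot(inherits(model, "slcnn"))
  val <- smooth_1d_value(model$W_spec, model$dims$C, model$config$N_spec)
  if (isTRUE(model$dims$use_img)) {
    val <- val + smooth_2d_value(model$W_img, model$dims$Cg, model$config$N_img)
  }
  val
}

# ---- model construction -----------------------------------------------------

new_slcnn <- function(config, dims, W_spec, b_spec, V, b_out,
                      W_img = NULL, b_img = NULL, label_levels,
                      loss_trace = numeric()) {
  structure(
    list(W_spec = W_spec, b_spec = b_spec, W_img = W_img, b_img = b_img,
         V = V, b_out = b_out, config = config, dims = dims,
         label_levels = label_levels, loss_trace = loss_trace),
    class = "slcnn"
  )
}

#' Build an SL-CNN from explicit weights
#'
#' Mainly for worked examples and tests: constructs a network with given
#' kernel/output weights instead of training one.
#'
#' @param config An `slcnn_config` (its `K_spec`, `N_spec`, `stride_s`, and
#'   image settings must match the supplied weight shapes).
#' @param input_shape List with `C` (spectral channels), `P` (bins), and
#'   optionally `contrasts`, `H`, `W` for the image branch.
#' @param W_spec `K_spec x (C * N_spec)` kernel matrix (channel-major
#'   columns).
#' @param b_spec Length-`K_spec` bias vector.
#' @param V `(merged feature length) x n_classes` output weight matrix.
#' @param b_out Length-`n_classes` output bias.
#' @param W_img,b_img Image-branch weights (`K_img x (Cg * N_img^2)`,
#'   column-major patch layout) when the branch is enabled.
#' @param label_levels Class vocabulary (column order of `V`).
#' @return An `slcnn` model.
#' @export
slcnn_from_weights <- function(config, input_shape, W_spec, b_spec, V, b_out,
                               W_img = NULL, b_img = NULL,
                               label_levels = colnames(V)) {
  dims <- slcnn_dims(config, input_shape$C, input_shape$P,
                     contrasts = input_shape$contrasts %||% character(),
                     H = input_shape$H, W = input_shape$W)
  stopifnot(nrow(W_spec) == config$K_spec,
            ncol(W_spec) == dims$C * config$N_spec,
            nrow(V) == dims$d)
  if (is.null(label_levels)) {
    label_levels <- paste0("class", seq_len(ncol(V)))
  }
  new_slcnn(config, dims, W_spec, b_spec, V, b_out, W_img, b_img, label_levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exposed forward ops ----------------------------------------------------

#' 1D convolution of a spectrum with a model's spectral kernels
#'
#' @param spectrum A numeric vector (single channel) or `channels x P`
#'   matrix matching the model input shape.
#' @param model An `slcnn`.
#' @param activation `"relu"` (default) or `"identity"` to inspect
#'   pre-activation values.
#' @return A `K_spec x F` feature map matrix with attribute
#'   `branch = "spectral"`.
#' @export
conv1d_forward <- function(spectrum, model, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is.vector(spectrum)) spectrum <- matrix(spectrum, nrow = 1)
  dims <- model$dims
  if (nrow(spectrum) != dims$C || ncol(spectrum) != dims$P) {
    abort(sprintf("spectrum shape %dx%d does not match model input %dx%d",
                  nrow(spectrum), ncol(spectrum), dims$C, dims$P))
  }
  flat <- matrix(as.vector(t(spectrum)), nrow = 1) # channel-major
  Z <- spec_design(flat, dims$C, dims$P, model$config$N_spec,
                   model$config$stride_s, dims$F_spec)
  A <- Z %*% t(model$W_spec)
  A <- sweep(A, 2, model$b_spec, "+")
  if (activation == "relu") A <- A * (A > 0)
  out <- t(A) # K x F
  attr(out, "branch") <- "spectral"
  out
}

#' 2D convolution + max pooling of image patches
#'
#' @param images Named list of `H x W` matrices (one per contrast, in the
#'   model's contrast order) or a `Cg x H x W` array.
#' @param model An `slcnn` with the image branch enabled.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return A `K_img x (Ph * Pw)` pooled feature map (pooled cells row-major)
#'   with attribute `branch = "image"`.
#' @export
conv2d_pool_forward <- function(images, model, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  dims <- model$dims
  if (!isTRUE(dims$use_img)) {
    abort("image branch disabled in this model; use spectral-only prediction")
  }
  if (is.list(images)) {
    images <- images[dims$contrasts]
    arr <- array(0, c(dims$Cg, dims$H, dims$W))
    for (g in seq_len(dims$Cg)) arr[g, , ] <- images[[g]]
    images <- arr
  }
  flat <- matrix(as.vector(aperm(images, c(2, 3, 1))), nrow = 1)
  # columns (g-1)*H*W + (w-1)*H + h, matching img_design
  Z <- img_design(flat, dims$Cg, dims$H, dims$W, model$config$N_img,
                  dims$Hc, dims$Wc)
  A <- Z %*% t(model$W_img)
  A <- sweep(A, 2, model$b_img, "+")
  if (activation == "relu") A <- A * (A > 0)
  cells <- pool_cells(dims$Hc, dims$Wc, dims$Ph, dims$Pw, model$config$pool_size)
  out <- matrix(0, model$config$K_img, length(cells))
  for (ci in seq_along(cells)) {
    out[, ci] <- apply(A[cells[[ci]], , drop = FALSE], 2, max)
  }
  attr(out, "branch") <- "image"
  out
}

#' Merge and flatten branch feature maps
#'
#' Concatenates the spectral map first (kernel-major, positions fastest),
#' then the image map. The index convention is exposed by
#' [feature_index_map()]: merged feature 0 is spectral kernel 0 at
#' position 0.
#'
#' @param spec_map `K x F` spectral feature map (from [conv1d_forward()]).
#' @param img_map Optional pooled image feature map.
#' @return Numeric vector of merged features.
#' @export
merge_flatten <- function(spec_map, img_map = NULL) {
  out <- as.vector(t(spec_map))
  if (!is.null(img_map)) out <- c(out, as.vector(t(img_map)))
  out
}

#' Index lookup from merged features to branch/kernel/position
#'
#' @param model An `slcnn`.
#' @return A tibble with one row per merged feature: `feature` (0-based
#'   merged index), `branch`, `kernel` (0-based), `position` (0-based;
#'   convolution position for the spectral branch, pooled cell for the
#'   image branch), and for spectral features the receptive field
#'   `start_bin`/`end_bin` (0-based, inclusive).
#' @export
feature_index_map <- function(model) {
  cfg <- model$config
  dims <- model$dims
  spec <- tidyr::expand_grid(kernel = seq_len(cfg$K_spec) - 1L,
                             position = seq_len(dims$F_spec) - 1L)
  spec <- dplyr::mutate(spec,
    feature = dplyr::row_number() - 1L,
    branch = "spectral",
    start_bin = .data$position * cfg$stride_s,
    end_bin = .data$position * cfg$stride_s + cfg$N_spec - 1L
  )
  out <- spec
  if (isTRUE(dims$use_img)) {
    img <- tidyr::expand_grid(kernel = seq_len(cfg$K_img) - 1L,
                              position = seq_len(dims$Ph * dims$Pw) - 1L)
    img <- dplyr::mutate(img,
      feature = nrow(spec) + dplyr::row_number() - 1L,
      branch = "image",
      start_bin = NA_integer_, end_bin = NA_integer_
    )
    out <- dplyr::bind_rows(spec, img)
  }
  dplyr::select(out, "feature", "branch", "kernel", "position",
                "start_bin", "end_bin")
}

# ---- loss and gradients -----------------------------------------------------

class_weight_vector <- function(labels, label_levels, class_weighting) {
  if (!class_weighting) return(rep(1, length(labels)))
  tab <- table(factor(labels, levels = label_levels))
  w_class <- length(labels) / (length(label_levels) * pmax(as.numeric(tab), 1))
  as.numeric(w_class[match(labels, label_levels)])
}

# loss + gradients for a batch given a precomputed design
slcnn_loss_grad <- function(model, design, y_idx, sample_w,
                            lambda1, lambda2, compute_grad = TRUE) {
  cfg <- model$config
  dims <- model$dims
  n <- design$n
  L <- length(model$label_levels)
  fwd <- slcnn_forward(model, design)
  p <- softmax_rows(fwd$logits)
  wsum <- sum(sample_w)
  ll <- -log(pmax(p[cbind(seq_len(n), y_idx)], 1e-300))
  data_loss <- sum(sample_w * ll) / wsum
  pen1 <- sum(model$W_spec^2) + sum(model$V^2) +
    if (isTRUE(dims$use_img)) sum(model$W_img^2) else 0
  pen2 <- smoothness_penalty(model)
  loss <- data_loss + lambda1 * pen1 + lambda2 * pen2
  if (!compute_grad) return(list(loss = loss, data_loss = data_loss))
  Y <- matrix(0, n, L)
  Y[cbind(seq_len(n), y_idx)] <- 1
  dlogits <- (p - Y) * (sample_w / wsum)
  gV <- t(fwd$Phi) %*% dlogits + 2 * lambda1 * model$V
  gb_out <- colSums(dlogits)
  dPhi <- dlogits %*% t(model$V)
  Fs <- dims$F_spec
  dPhi_s <- dPhi[, seq_len(dims$d_spec), drop = FALSE]
  # back to (F, n, K) row layout of A_s
  dH_s <- matrix(aperm(array(dPhi_s, c(n, Fs, cfg$K_spec)), c(2, 1, 3)),
                 nrow = n * Fs)
  dA_s <- dH_s * (fwd$cache$A_s > 0)
  gW_spec <- t(dA_s) %*% design$Zs + 2 * lambda1 * model$W_spec +
    lambda2 * smooth_1d_grad(model$W_spec, dims$C, cfg$N_spec)
  gb_spec <- colSums(dA_s)
  grads <- list(W_spec = gW_spec, b_spec = gb_spec, V = gV, b_out = gb_out)
  if (isTRUE(dims$use_img)) {
    Fi <- dims$F_img
    dPhi_i <- dPhi[, dims$d_spec + seq_len(dims$d_img), drop = FALSE]
    n_cells <- dims$Ph * dims$Pw
    dPooled <- aperm(array(dPhi_i, c(n, n_cells, cfg$K_img)), c(1, 3, 2))
    dH_i <- matrix(0, n * Fi, cfg$K_img)
    cells <- fwd$cache$cells
    argmax <- fwd$cache$argmax
    for (ci in seq_len(n_cells)) {
      S <- cells[[ci]]
      for (k in seq_len(cfg$K_img)) {
        pos <- S[argmax[, k, ci]]
        rows <- (seq_len(n) - 1L) * Fi + pos
        dH_i[cbind(rows, k)] <- dH_i[cbind(rows, k)] + dPooled[, k, ci]
      }
    }
    dA_i <- dH_i * (fwd$cache$A_i > 0)
    grads$W_img <- t(dA_i) %*% design$Zi + 2 * lambda1 * model$W_img +
      lambda2 * smooth_2d_grad(model$W_img, dims$Cg, cfg$N_img)
    grads$b_img <- colSums(dA_i)
  }
  list(loss = loss, data_loss = data_loss, grads = grads)
}

#' Regularized training loss of an SL-CNN on a dataset
#'
#' Weighted mean categorical cross-entropy plus `lambda1` weight decay and
#' `lambda2` neighbor-smoothness penalty (biases enter neither penalty).
#'
#' @param model An `slcnn`.
#' @param ds An `mrsi_dataset` with labels in the model vocabulary.
#' @param lambda1,lambda2 Penalty strengths; default to the model config.
#' @param class_weighting Override the config's class weighting.
#' @return Scalar loss.
#' @export
slcnn_loss <- function(model, ds, lambda1 = model$config$lambda1,
                       lambda2 = model$config$lambda2,
                       class_weighting = model$config$class_weighting) {
  design <- slcnn_design(ds, model$config, model$dims)
  y_idx <- match(ds$meta$label, model$label_levels)
  if (anyNA(y_idx)) abort("dataset labels outside the model vocabulary")
  w <- class_weight_vector(ds$meta$label, model$label_levels, class_weighting)
  slcnn_loss_grad(model, design, y_idx, w, lambda1, lambda2,
                  compute_grad = FALSE)$loss
}

# flat parameter packing, used by the finite-difference gradient checks
flatten_params <- function(model) {
  v <- c(as.vector(model$W_spec), model$b_spec,
         as.vector(model$V), model$b_out)
  if (isTRUE(model$dims$use_img)) {
    v <- c(v, as.vector(model$W_img), model$b_img)
  }
  v
}

set_params <- function(model, v) {
  i <- 0
  take <- function(k) {
    out <- v[i + seq_len(k)]
    i <<- i + k
    out
  }
  model$W_spec <- matrix(take(length(model$W_spec)), nrow(model$W_spec))
  model$b_spec <- take(length(model$b_spec))
  model$V <- matrix(take(length(model$V)), nrow(model$V))
  model$b_out <- take(length(model$b_out))
  if (isTRUE(model$dims$use_img)) {
    model$W_img <- matrix(take(length(model$W_img)), nrow(model$W_img))
    model$b_img <- take(length(model$b_img))
  }
  model
}

grads_to_vector <- function(grads, use_img) {
  v <- c(as.vector(grads$W_spec), grads$b_spec,
         as.vector(grads$V), grads$b_out)
  if (use_img) v <- c(v, as.vector(grads$W_img), grads$b_img)
  v
}

# ---- training ---------------------------------------------------------------

init_slcnn <- function(config, dims, label_levels) {
  L <- length(label_levels)
  fan_s <- dims$C * config$N_spec
  W_spec <- matrix(runif(config$K_spec * fan_s, -1, 1) / sqrt(fan_s),
                   nrow = config$K_spec)
  V <- matrix(runif(dims$d * L, -1, 1) / sqrt(dims$d), nrow = dims$d)
  W_img <- NULL; b_img <- NULL
  if (isTRUE(dims$use_img)) {
    fan_i <- dims$Cg * config$N_img^2
    W_img <- matrix(runif(config$K_img * fan_i, -1, 1) / sqrt(fan_i),
                    nrow = config$K_img)
    b_img <- rep(0, config$K_img)
  }
  new_slcnn(config, dims, W_spec, rep(0, config$K_spec), V, rep(0, L),
            W_img, b_img, label_levels)
}

#' Train the single-layer CNN
#'
#' Plain mini-batch gradient descent at fixed learning rate on the
#' regularized, class-weighted cross-entropy. Initialization and batch
#' order are seeded, so identical `(dataset, config)` yields an identical
#' model.
#'
#' @param ds An `mrsi_dataset` with at least two classes present.
#' @param config An `slcnn_config`. The image branch is used when
#'   `K_img > 0` and the dataset carries image patches.
#' @return A trained `slcnn`; `$loss_trace` holds the full-dataset loss
#'   after each epoch.
#' @export
slcnn_train <- function(ds, config = slcnn_config()) {
  labels_present <- unique(ds$meta$label)
  if (length(labels_present) < 2) abort("training data must contain >= 2 classes")
  dm <- dim(ds$spectra)
  contrasts <- if (config$K_img > 0) names(ds$images) else character()
  if (config$K_img > 0 && length(contrasts) == 0) {
    abort("K_img > 0 but the dataset has no image patches")
  }
  H <- if (length(contrasts) > 0) dim(ds$images[[1]])[2] else NULL
  W <- if (length(contrasts) > 0) dim(ds$images[[1]])[3] else NULL
  dims <- slcnn_dims(config, dm[2], dm[3], contrasts, H, W)
  design <- slcnn_design(ds, config, dims)
  label_levels <- intersect(ds$label_levels, labels_present)
  y_idx <- match(ds$meta$label, label_levels)
  w_all <- class_weight_vector(ds$meta$label, label_levels, config$class_weighting)
  n <- design$n
  Fs <- dims$F_spec
  Fi <- if (isTRUE(dims$use_img)) dims$F_img else 0L
  withr::with_seed(config$seed, {
    model <- init_slcnn(config, dims, label_levels)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (st in starts) {
        b <- ord[st:min(st + config$batch_size - 1L, n)]
        sub <- list(
          Zs = design$Zs[rep((b - 1L) * Fs, each = Fs) + seq_len(Fs), , drop = FALSE],
          Zi = if (Fi > 0) {
            design$Zi[rep((b - 1L) * Fi, each = Fi) + seq_len(Fi), , drop = FALSE]
          },
          n = length(b)
        )
        res <- slcnn_loss_grad(model, sub, y_idx[b], w_all[b],
                               config$lambda1, config$lambda2)
        if (!is.finite(res$loss)) {
          abort(sprintf(
            "non-finite loss at epoch %d; try a smaller learning rate eta", ep
          ))
        }
        g <- res$grads
        model$W_spec <- model$W_spec - config$eta * g$W_spec
        model$b_spec <- model$b_spec - config$eta * g$b_spec
        model$V <- model$V - config$eta * g$V
        model$b_out <- model$b_out - config$eta * g$b_out
        if (Fi > 0) {
          model$W_img <- model$W_img - config$eta * g$W_img
          model$b_img <- model$b_img - config$eta * g$b_img
        }
      }
      trace[ep] <- slcnn_loss_grad(model, design, y_idx, w_all,
                                   config$lambda1, config$lambda2,
                                   compute_grad = FALSE)$loss
      if (!is.finite(trace[ep])) {
        abort(sprintf(
          "non-finite loss at epoch %d; try a smaller learning rate eta", ep
        ))
      }
    }
    model$loss_trace <- trace
    model
  })
}

#' Predict class probabilities for voxels
#'
#' Softmax over the output-layer logits; probabilities sum to one and the
#' arg-max defines the predicted label.
#'
#' @param object A trained `slcnn`.
#' @param newdata An `mrsi_dataset` with matching modality shapes.
#' @param type `"tibble"` (default: voxel ids, predicted class and one
#'   `score_<class>` probability column per class) or `"prob"` for the bare
#'   probability matrix.
#' @param ... Unused.
#' @return A tibble or matrix of class probabilities.
#' @export
predict.slcnn <- function(object, newdata, type = c("tibble", "prob"), ...) {
  type <- match.arg(type)
  dm <- dim(newdata$spectra)
  if (dm[2] != object$dims$C || dm[3] != object$dims$P) {
    abort("newdata spectra shape does not match the model")
  }
  design <- slcnn_design(newdata, object$config, object$dims)
  p <- softmax_rows(slcnn_forward(object, design)$logits)
  colnames(p) <- object$label_levels
  if (type == "prob") return(p)
  pred <- object$label_levels[max.col(p, ties.method = "first")]
  scores <- tibble::as_tibble(p, .name_repair = "minimal")
  names(scores) <- paste0("score_", object$label_levels)
  dplyr::bind_cols(
    tibble::tibble(voxel_id = newdata$meta$voxel_id, predicted = pred),
    scores
  )
}

#' @export
print.slcnn <- function(x, ...) {
  cat(sprintf(
    "<slcnn> %d spectral kernel(s) (N = %d, stride = %d) over %d channel(s) x %d bins\n",
    x$config$K_spec, x$config$N_spec, x$config$stride_s, x$dims$C, x$dims$P
  ))
  if (isTRUE(x$dims$use_img)) {
    cat(sprintf("  image branch: %d kernel(s) %dx%d, pool %d, contrasts: %s\n",
                x$config$K_img, x$config$N_img, x$config$N_img,
                x$config$pool_size, paste(x$dims$contrasts, collapse = ", ")))
  }
  cat(sprintf("  merged features: %d; classes: %s\n", x$dims$d,
              paste(x$label_levels, collapse = ", ")))
  if (length(x$loss_trace) > 0) {
    cat(sprintf("  final training loss: %.4f after %d epochs\n",
                x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  }
  invisible(x)
}

#' @exportS3Method tidy slcnn
#' @describeIn slcnn_train Tidy view of learned kernel weights: one row per
#'   weight with branch, kernel, channel and offset indices.
#' @param x An `slcnn`.
#' @param ... Unused.
#' @export
tidy.slcnn <- function(x, ...) {
  cfg <- x$config
  out <- tidyr::expand_grid(
    kernel = seq_len(cfg$K_spec) - 1L,
    channel = seq_len(x$dims$C),
    offset = seq_len(cfg$N_spec) - 1L
  )
  out$branch <- "spectral"
  # column layout of W_spec is (channel-1)*N + offset within each kernel row
  out$weight <- purrr::pmap_dbl(out, function(kernel, channel, offset, ...) {
    x$W_spec[kernel + 1L, (channel - 1L) * cfg$N_spec + offset + 1L]
  })
  dplyr::select(out, "branch", "kernel", "channel", "offset", "weight")
}

#' @exportS3Method glance slcnn
#' @describeIn slcnn_train One-row model summary (dimensions, final loss,
#'   penalty values).
#' @export
glance.slcnn <- function(x, ...) {
  tibble::tibble(
    n_features = x$dims$d,
    n_classes = length(x$label_levels),
    epochs = x$config$epochs,
    final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA_real_,
    smoothness = smoothness_penalty(x)
  )
}

#' @exportS3Method autoplot slcnn
#' @describeIn slcnn_train Plot the learned spectral kernels as weight
#'   profiles over the kernel window.
#' @param object An `slcnn`.
#' @export
autoplot.slcnn <- function(object, ...) {
  df <- tidy.slcnn(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$weight,
                                   colour = factor(.data$kernel))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "kernel offset (bins)", y = "weight",
                  colour = "kernel") +
    ggplot2::theme_minimal()
}
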