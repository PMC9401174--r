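# shared fixtures and independent oracles, all built in code

# deterministic 4-voxel dataset: 2 patients, 2 classes, spectra + one contrast
make_tiny_dataset <- function(with_images = TRUE) {
  meta <- tibble::tibble(
    voxel_id = c("v1", "v2", "v3", "v4"),
    patient_id = c("p1", "p1", "p2", "p2"),
    roi_id = NA_character_,
    label = c("a", "a", "b", "b")
  )
  spectra <- array(0, dim = c(4, 1, 6))
  spectra[, 1, ] <- matrix(seq_len(24) / 10, nrow = 4, byrow = TRUE)
  images <- list()
  if (with_images) {
    arr <- array(0, dim = c(4, 2, 2))
    arr[, , ] <- matrix(seq_len(16) / 4, nrow = 4)
    images <- list(T1 = arr)
  }
  mrsi_dataset(meta, spectra, images = images,
               ppm_axis = seq(4, 1, length.out = 6))
}

# small two-class synthetic cohort used across tests
quick_cfg <- function(seed = 1, n_pat = 4, n_vox = 5, effect = 1.8,
                      patient_sd = 0.1, noise = 0.03, P = 40,
                      image_shape = NULL, image_effect = 0) {
  synthetic_config(
    P = P,
    peaks = tibble::tibble(name = c("A", "B"),
                           center_bin = c(round(P * 0.25), round(P * 0.7)),
                           width_bins = c(2, 3),
                           base_amplitude = c(1, 0.8)),
    class_effects = list(neg = c(A = 1), pos = c(A = effect)),
    n_patients_per_class = c(neg = n_pat, pos = n_pat),
    voxels_per_patient = c(neg = n_vox, pos = n_vox),
    patient_effect_sd = patient_sd, noise_sd = noise,
    image_shape = image_shape, contrasts = "T1",
    image_class_effect = c(neg = 0, pos = image_effect),
    seed = seed
  )
}

# naive 1D valid convolution oracle (loops; ReLU optional)
oracle_conv1d <- function(spectrum, W, b, s, relu = TRUE) {
  if (is.vector(spectrum)) spectrum <- matrix(spectrum, nrow = 1)
  C <- nrow(spectrum); P <- ncol(spectrum)
  N <- ncol(W) / C
  F_out <- (P - N) %/% s + 1
  out <- matrix(0, nrow(W), F_out)
  for (k in seq_len(nrow(W))) {
    for (j in seq_len(F_out)) {
      acc <- b[k]
      for (ch in seq_len(C)) {
        for (i in seq_len(N)) {
          acc <- acc + W[k, (ch - 1) * N + i] * spectrum[ch, (j - 1) * s + i]
        }
      }
      out[k, j] <- if (relu) max(acc, 0) else acc
    }
  }
  out
}

# naive 2D conv + non-overlapping max pooling oracle
oracle_conv2d_pool <- function(images, W, b, N, pool, relu = TRUE) {
  Cg <- length(images)
  H <- nrow(images[[1]]); Wd <- ncol(images[[1]])
  Hc <- H - N + 1; Wc <- Wd - N + 1
  K <- nrow(W)
  conv <- array(0, c(K, Hc, Wc))
  for (k in seq_len(K)) {
    for (u in seq_len(Hc)) for (v in seq_len(Wc)) {
      acc <- b[k]
      for (g in seq_len(Cg)) {
        patch <- images[[g]][u:(u + N - 1), v:(v + N - 1)]
        kw <- matrix(W[k, (g - 1) * N * N + seq_len(N * N)], N, N)
        acc <- acc + sum(patch * kw)
      }
      conv[k, u, v] <- if (relu) max(acc, 0) else acc
    }
  }
  Ph <- Hc %/% pool; Pw <- Wc %/% pool
  out <- matrix(0, K, Ph * Pw)
  for (k in seq_len(K)) {
    for (pu in seq_len(Ph)) for (pv in seq_len(Pw)) {
      blk <- conv[k, (pu - 1) * pool + seq_len(pool),
                  (pv - 1) * pool + seq_len(pool)]
      out[k, (pu - 1) * Pw + pv] <- max(blk)
    }
  }
  out
}

# central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# random small slcnn model (optionally with image branch) for property tests
random_model <- function(seed, P = 20, C = 1, K = 2, N = 4, s = 3,
                         with_images = FALSE, Kimg = 2, Nimg = 2, pool = 2,
                         H = 5, Wd = 5, n_classes = 2) {
  withr::with_seed(seed, {
    cfg <- slcnn_config(K_spec = K, N_spec = N, stride_s = s,
                        K_img = if (with_images) Kimg else 0L,
                        N_img = Nimg, pool_size = pool)
    input <- list(C = C, P = P)
    if (with_images) {
      input$contrasts <- c("T1")
      input$H <- H; input$W <- Wd
    }
    Fs <- conv_output_length(P, N, s)
    d <- K * Fs
    W_img <- NULL; b_img <- NULL
    if (with_images) {
      Hc <- H - Nimg + 1; Wc <- Wd - Nimg + 1
      d <- d + Kimg * (Hc %/% pool) * (Wc %/% pool)
      W_img <- matrix(rnorm(Kimg * Nimg^2), Kimg)
      b_img <- rnorm(Kimg)
    }
    slcnn_from_weights(
      cfg, input,
      W_spec = matrix(rnorm(K * C * N), K),
      b_spec = rnorm(K),
      V = matrix(rnorm(d * n_classes), d),
      b_out = rnorm(n_classes),
      W_img = W_img, b_img = b_img,
      label_levels = paste0("c", seq_len(n_classes))
    )
  })
}

# closed-form MCC from confusion counts (test-side oracle)
mcc_formula <- function(tp, fn, fp, tn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# exhaustive concordant-pair AUC oracle
auc_pairs <- function(truth, scores, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# naive structural-components DeLong oracle (double loops)
delong_naive <- function(scores_a, scores_b, truth, positive) {
  is_pos <- truth == positive
  comp <- function(s) {
    X <- s[is_pos]; Y <- s[!is_pos]
    m <- length(X); n <- length(Y)
    V10 <- vapply(X, function(x) mean((x > Y) + 0.5 * (x == Y)), 0)
    V01 <- vapply(Y, function(y) mean((X > y) + 0.5 * (X == y)), 0)
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  a <- comp(scores_a); b <- comp(scores_b)
  m <- sum(is_pos); n <- sum(!is_pos)
  S10 <- stats::cov(cbind(a$V10, b$V10))
  S01 <- stats::cov(cbind(a$V01, b$V01))
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  list(delta = a$auc - b$auc, variance = v)
}
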