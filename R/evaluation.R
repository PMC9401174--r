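#' Restrict a dataset to a pairwise task
#'
#' Classification is evaluated pairwise (e.g. grade II vs grade III); this
#' keeps only the voxels of the named classes and sets the vocabulary to
#' them, in the given order (second class = positive).
#'
#' @param ds An `mrsi_dataset`.
#' @param classes Character vector of classes to keep (usually length 2).
#' @return The restricted `mrsi_dataset`.
#' @export
subset_classes <- function(ds, classes) {
  missing_cls <- setdiff(classes, ds$label_levels)
  if (length(missing_cls) > 0) {
    abort(paste0("unknown class(es): ", paste(missing_cls, collapse = ", ")))
  }
  out <- subset_voxels(ds, which(ds$meta$label %in% classes))
  out$label_levels <- classes
  out
}

# ---- fold plans -------------------------------------------------------------

new_fold_plan <- function(df, protocol) {
  structure(df, class = c("fold_plan", class(df)), protocol = protocol)
}

fold_from_test_patients <- function(ds, test_pat_list, protocol) {
  all_pat <- patient_ids(ds)
  df <- purrr::imap_dfr(test_pat_list, function(tp, i) {
    tibble::tibble(
      fold = as.integer(i),
      test_patients = list(tp),
      train_patients = list(setdiff(all_pat, tp)),
      test_voxels = list(ds$meta$voxel_id[ds$meta$patient_id %in% tp])
    )
  })
  new_fold_plan(df, protocol)
}

check_train_classes <- function(ds, plan) {
  classes <- unique(ds$meta$label)
  for (i in seq_len(nrow(plan))) {
    train_lab <- unique(ds$meta$label[ds$meta$patient_id %in% plan$train_patients[[i]] &
                                        !ds$meta$voxel_id %in% plan$test_voxels[[i]]])
    miss <- setdiff(classes, train_lab)
    if (length(miss) > 0) {
      abort(sprintf("fold %d: class '%s' absent from the training split",
                    plan$fold[i], miss[1]))
    }
  }
  invisible(plan)
}

#' Leave-one-patient-out fold plan
#'
#' One fold per patient: all of that patient's voxels form the test set and
#' every other patient trains — the grouping that prevents patient-identity
#' leakage.
#'
#' @param ds An `mrsi_dataset` with >= 2 patients.
#' @return A `fold_plan` tibble (`fold`, `train_patients`, `test_patients`,
#'   `test_voxels`).
#' @export
lopo_folds <- function(ds) {
  pats <- patient_ids(ds)
  if (length(pats) < 2) abort("need at least two patients for LOPO")
  plan <- fold_from_test_patients(ds, as.list(pats), "lopo")
  check_train_classes(ds, plan)
}

#' Patient-grouped k-fold plan
#'
#' Patients are partitioned into `k` folds, stratified by each patient's
#' majority class; voxels follow their patient.
#'
#' @param ds An `mrsi_dataset`.
#' @param k Number of folds (default 3).
#' @param seed Seed for the patient shuffle.
#' @return A `fold_plan`.
#' @export
grouped_kfold <- function(ds, k = 3L, seed = 1L) {
  pats <- dplyr::count(ds$meta, .data$patient_id, .data$label)
  pats <- dplyr::slice_max(dplyr::group_by(pats, .data$patient_id),
                           .data$n, n = 1, with_ties = FALSE)
  pats <- dplyr::ungroup(pats)
  if (k > nrow(pats)) abort("k exceeds the number of patients")
  assignment <- withr::with_seed(seed, {
    out <- character(0)
    ids <- character(0)
    for (cl in unique(pats$label)) {
      p <- sample(pats$patient_id[pats$label == cl])
      ids <- c(ids, p)
      out <- c(out, rep_len(seq_len(k), length(p)))
    }
    setNames(as.integer(out), ids)
  })
  test_sets <- purrr::map(seq_len(k), function(f) names(assignment)[assignment == f])
  plan <- fold_from_test_patients(ds, test_sets, "grouped_kfold")
  check_train_classes(ds, plan)
}

#' Naive voxel-level k-fold plan
#'
#' Voxels are partitioned at random with no regard for patients, so voxels
#' of one patient can sit on both sides of a fold. This is the leakage-prone
#' protocol the patient-grouped plans exist to replace; it is provided to
#' demonstrate the optimistic bias on patient-confounded data.
#'
#' @param ds An `mrsi_dataset`.
#' @param k Number of folds.
#' @param seed Seed for the voxel shuffle.
#' @return A `fold_plan` (train/test patient sets may overlap).
#' @export
voxel_kfold <- function(ds, k = 3L, seed = 1L) {
  n <- n_voxels(ds)
  if (k > n) abort("k exceeds the number of voxels")
  fold_of <- withr::with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  df <- purrr::map_dfr(seq_len(k), function(f) {
    test_vox <- ds$meta$voxel_id[fold_of == f]
    tibble::tibble(
      fold = as.integer(f),
      test_patients = list(unique(ds$meta$patient_id[fold_of == f])),
      train_patients = list(unique(ds$meta$patient_id[fold_of != f])),
      test_voxels = list(test_vox)
    )
  })
  new_fold_plan(df, "voxel_kfold")
}

# ---- metrics ----------------------------------------------------------------

#' Matthews correlation coefficient
#'
#' Binary MCC `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced score in `[-1, 1]` usable under strong class imbalance. Any
#' zero factor in the denominator yields 0 by convention (e.g. all-one-class
#' predictions).
#'
#' @param truth,predicted Equal-length label vectors over at most two
#'   classes.
#' @param positive Optional positive-class label; the value of MCC does not
#'   depend on it.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' mcc(c("a", "a", "b", "b"), c("a", "a", "b", "a"))
#' @export
mcc <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  levs <- sort(unique(c(truth, predicted)))
  if (length(levs) > 2) abort("mcc is defined for binary tasks")
  if (length(levs) == 1) return(0)
  pos <- positive %||% levs[2]
  tp <- sum(truth == pos & predicted == pos)
  tn <- sum(truth != pos & predicted != pos)
  fp <- sum(truth != pos & predicted == pos)
  fn <- sum(truth == pos & predicted != pos)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(denom)
}

#' ROC curve and area under it
#'
#' AUC equals the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counted one half; the curve lists one
#' point per distinct threshold.
#'
#' @param truth Binary label vector.
#' @param scores Real-valued scores, higher meaning more positive.
#' @param positive Positive-class label; defaults to the second sorted
#'   level.
#' @return A list of class `roc_result`: `auc`, `curve` (tibble with
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(truth, scores, positive = NULL) {
  if (length(truth) != length(scores)) {
    abort("truth and scores must have equal length")
  }
  truth <- as.character(truth)
  levs <- sort(unique(truth))
  if (length(levs) < 2) abort("ROC is undefined for single-class truth")
  if (length(levs) > 2) abort("ROC is defined for binary tasks")
  pos <- positive %||% levs[2]
  is_pos <- truth == pos
  m <- sum(is_pos); n <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_pos]) - m * (m + 1) / 2) / (m * n)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- purrr::map_dfr(c(Inf, th), function(t0) {
    tibble::tibble(
      threshold = t0,
      fpr = sum(scores[!is_pos] >= t0) / n,
      tpr = sum(scores[is_pos] >= t0) / m
    )
  })
  structure(list(auc = auc, curve = curve, n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# mid-rank placement components of the AUC (per modality)
delong_placements <- function(scores, is_pos) {
  X <- scores[is_pos]; Y <- scores[!is_pos]
  m <- length(X); n <- length(Y)
  r_all <- rank(c(X, Y), ties.method = "average")
  r_x <- rank(X, ties.method = "average")
  r_y <- rank(Y, ties.method = "average")
  V10 <- (r_all[seq_len(m)] - r_x) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(V10 = V10, V01 = V01, auc = sum(V10) / m)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples
#' using the fast mid-rank form of the structural-components covariance;
#' returns a two-sided normal p-value for the AUC difference.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param truth Binary truth labels.
#' @param positive Positive-class label (default second sorted level).
#' @return One-row tibble: `auc_a`, `auc_b`, `delta_auc`, `variance`,
#'   `statistic`, `p_value`. Identical score vectors give `delta_auc = 0`
#'   and `p_value = 1` by convention.
#' @export
delong_test <- function(scores_a, scores_b, truth, positive = NULL) {
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth)) {
    abort("scores and truth must have equal length")
  }
  truth <- as.character(truth)
  levs <- sort(unique(truth))
  if (length(levs) != 2) abort("DeLong test requires binary truth")
  pos <- positive %||% levs[2]
  is_pos <- truth == pos
  pa <- delong_placements(scores_a, is_pos)
  pb <- delong_placements(scores_b, is_pos)
  if (identical(scores_a, scores_b)) {
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = 0,
                          variance = 0, statistic = 0, p_value = 1))
  }
  m <- sum(is_pos); n <- sum(!is_pos)
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(delta) < 1e-12) {
      return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                            variance = 0, statistic = 0, p_value = 1))
    }
    abort("degenerate variance estimate for differing score vectors")
  }
  z <- delta / sqrt(v)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                 variance = v, statistic = z,
                 p_value = 2 * pnorm(-abs(z)))
}

# ---- method adapters --------------------------------------------------------

new_mrsi_method <- function(name, fit, predict, default_params = list(),
                            complexity = function(params) 0) {
  structure(list(name = name, fit = fit, predict = predict,
                 default_params = default_params, complexity = complexity),
            class = "mrsi_method")
}

#' SL-CNN as an evaluation-harness method
#'
#' Wraps [slcnn_train()]/[predict.slcnn()] behind the common method
#' interface used by [nested_cv()] and [rgs_search()]. Grid parameters
#' override fields of the base config (`K_spec`, `N_spec`, `stride_s`,
#' `eta`, `lambda1`, `lambda2`, ...).
#'
#' @param config Base `slcnn_config`.
#' @return An `mrsi_method`.
#' @export
method_slcnn <- function(config = slcnn_config()) {
  new_mrsi_method(
    "slcnn",
    fit = function(train, params) {
      cfg <- do.call(slcnn_config, modifyList(unclass(config), params))
      slcnn_train(train, cfg)
    },
    predict = function(model, test) predict(model, test),
    default_params = list(),
    complexity = function(params) {
      (params$K_spec %||% config$K_spec) + (params$K_img %||% config$K_img)
    }
  )
}

#' RBF-SVM as an evaluation-harness method
#'
#' @param C,gamma Defaults for the SVM parameters (overridable by the grid;
#'   `gamma = NULL` means `1 / n_features`).
#' @param modalities Which modality streams to concatenate.
#' @return An `mrsi_method`.
#' @export
method_svm_rbf <- function(C = 1, gamma = NULL, modalities = "all") {
  new_mrsi_method(
    "svm_rbf",
    fit = function(train, params) {
      list(train = train,
           C = params$C %||% C, gamma = params$gamma %||% gamma)
    },
    predict = function(model, test) {
      out <- svm_rbf_classify(model$train, test, C = model$C,
                              gamma = model$gamma, modalities = modalities)
      dplyr::select(out, -"patient_id", -"truth")
    },
    complexity = function(params) 0
  )
}

pls_block_list <- function(ds, modalities) {
  blocks <- list()
  if (modalities %in% c("all", "spectra")) {
    blocks$spectra <- concatenate_modalities(ds, "spectra")
  }
  if (modalities %in% c("all", "images") && length(ds$images) > 0) {
    blocks$images <- concatenate_modalities(ds, "images")
  }
  blocks
}

#' PLS-DA as an evaluation-harness method
#'
#' @param A Default number of latent components.
#' @param modalities Modality streams to concatenate.
#' @return An `mrsi_method`.
#' @export
method_pls_da <- function(A = 2L, modalities = "all") {
  new_mrsi_method(
    "pls_da",
    fit = function(train, params) {
      X <- concatenate_modalities(train, modalities)
      list(fit = pls_da_fit(X, factor(train$meta$label, train$label_levels),
                            A = params$A %||% A))
    },
    predict = function(model, test) {
      X <- concatenate_modalities(test, modalities)
      dplyr::bind_cols(tibble::tibble(voxel_id = test$meta$voxel_id),
                       predict(model$fit, X))
    },
    complexity = function(params) params$A %||% A
  )
}

#' Kernel PLS-DA (RBF) as an evaluation-harness method
#'
#' @param gamma Default RBF width.
#' @param A Default number of components.
#' @param modalities Modality streams to concatenate before the kernel.
#' @return An `mrsi_method`.
#' @export
method_kpls_da <- function(gamma = 0.01, A = 2L, modalities = "all") {
  new_mrsi_method(
    "kpls_da",
    fit = function(train, params) {
      X <- concatenate_modalities(train, modalities)
      g <- params$gamma %||% gamma
      K <- rbf_kernel_matrix(X, gamma = g)
      list(fit = kpls_da_fit(K, factor(train$meta$label, train$label_levels),
                             A = params$A %||% A),
           X = X, gamma = g)
    },
    predict = function(model, test) {
      Kt <- rbf_kernel_matrix(concatenate_modalities(test, modalities),
                              model$X, gamma = model$gamma)
      dplyr::bind_cols(tibble::tibble(voxel_id = test$meta$voxel_id),
                       predict(model$fit, Kt))
    },
    complexity = function(params) params$A %||% A
  )
}

#' Multi-block PLS-DA as an evaluation-harness method
#'
#' Spectra and images enter as separate blocks, scaled by block weights
#' (tunable through the grid as `w_spectra`; `w_images = 1 - w_spectra`).
#'
#' @param A Default number of components.
#' @param w_spectra Default spectra block weight in `[0, 1]`.
#' @return An `mrsi_method`.
#' @export
method_mbpls_da <- function(A = 2L, w_spectra = 0.5) {
  new_mrsi_method(
    "mbpls_da",
    fit = function(train, params) {
      blocks <- pls_block_list(train, "all")
      w <- params$w_spectra %||% w_spectra
      bw <- if (length(blocks) == 2) c(w, 1 - w) else 1
      list(fit = mbpls_da_fit(blocks, factor(train$meta$label, train$label_levels),
                              A = params$A %||% A, block_weights = bw))
    },
    predict = function(model, test) {
      blocks <- pls_block_list(test, "all")
      dplyr::bind_cols(tibble::tibble(voxel_id = test$meta$voxel_id),
                       predict(model$fit, blocks))
    },
    complexity = function(params) params$A %||% A
  )
}

# ---- hyper-parameter search -------------------------------------------------

draw_configurations <- function(grid, n_draws, seed) {
  combos <- prod(lengths(grid))
  if (combos <= n_draws) {
    all_cfg <- do.call(tidyr::expand_grid, grid)
    return(purrr::map(seq_len(nrow(all_cfg)), function(i) as.list(all_cfg[i, ])))
  }
  withr::with_seed(seed, {
    seen <- character(0)
    out <- list()
    while (length(out) < n_draws) {
      cand <- purrr::map(grid, function(v) v[[sample.int(length(v), 1)]])
      key <- paste(purrr::map_chr(cand, ~ format(.x, digits = 15)), collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cand
      }
    }
    out
  })
}

#' Random grid search with grouped inner cross-validation
#'
#' Draws `n_draws` hyper-parameter configurations uniformly from the grid
#' (all of them when the grid is small), scores each by pooled MCC under a
#' patient-grouped inner k-fold on the training patients only, and returns
#' the best. Ties are broken by smaller model complexity, then draw order.
#'
#' @param method An `mrsi_method`.
#' @param train An `mrsi_dataset` (the outer-fold training patients).
#' @param grid Named list of candidate value vectors; `NULL` or a
#'   single-combination grid short-circuits the search.
#' @param inner_k Inner folds (default 3).
#' @param n_draws Configurations to draw (default 30).
#' @param seed Seed for drawing and inner-fold assignment.
#' @return List with `params` (winning configuration), `inner_mcc`, a
#'   `results` tibble over candidates, and `patients_seen` (every patient
#'   id touched — the no-leakage instrumentation).
#' @export
rgs_search <- function(method, train, grid, inner_k = 3L, n_draws = 30L,
                       seed = 1L) {
  patients_seen <- patient_ids(train)
  if (is.null(grid) || length(grid) == 0 || prod(lengths(grid)) == 1) {
    params <- if (is.null(grid)) list() else purrr::map(grid, 1)
    return(list(params = params, inner_mcc = NA_real_,
                results = tibble::tibble(), patients_seen = patients_seen))
  }
  cands <- draw_configurations(grid, n_draws, seed)
  plan <- grouped_kfold(train, k = inner_k, seed = seed)
  scored <- purrr::imap(cands, function(params, i) {
    preds <- purrr::map_dfr(seq_len(nrow(plan)), function(f) {
      tr <- subset_voxels(train, which(!train$meta$voxel_id %in% plan$test_voxels[[f]]))
      te <- subset_voxels(train, match(plan$test_voxels[[f]], train$meta$voxel_id))
      sc <- fit_rescaler(tr)
      tr <- apply_rescaler(tr, sc)
      te <- apply_rescaler(te, sc)
      fit_params <- c(params, list(seed = seed * 131L %% 100000L + f))
      model <- method$fit(tr, fit_params)
      out <- method$predict(model, te)
      out$truth <- te$meta$label[match(out$voxel_id, te$meta$voxel_id)]
      out
    })
    tibble::tibble(
      draw = i,
      inner_mcc = mcc(preds$truth, preds$predicted),
      complexity = method$complexity(params),
      params = list(params)
    )
  })
  tab <- dplyr::bind_rows(scored)
  ord <- order(-tab$inner_mcc, tab$complexity, tab$draw)
  best <- tab[ord[1], ]
  list(params = best$params[[1]], inner_mcc = best$inner_mcc,
       results = tab, patients_seen = patients_seen)
}

# ---- nested cross-validation ------------------------------------------------

#' Nested cross-validation with a grouped outer protocol
#'
#' For every outer fold: run [rgs_search()] on the training patients only,
#' refit on all training patients with the winning configuration (unit
#' rescaling fitted on the training split and applied unchanged to the
#' held-out voxels), and predict the held-out patients. Pooled
#' out-of-fold predictions are scored by MCC; the whole procedure repeats
#' over `repetitions` seeds for a mean and sd.
#'
#' @param method An `mrsi_method`.
#' @param ds An `mrsi_dataset`.
#' @param grid Hyper-parameter grid for the inner search (`NULL` = use
#'   method defaults, no search).
#' @param protocol `"lopo"`, `"kfold3"` (patient-grouped) or
#'   `"kfold3_naive"` (voxel-level, leakage-prone — for demonstration).
#' @param repetitions Number of repeats `R` (seeds `seed`, `seed + 1`, ...).
#' @param seed Base seed.
#' @param inner_k,n_draws Inner-search controls.
#' @param k Outer folds for the k-fold protocols.
#' @param rescale Fit-and-apply unit-interval rescaling per fold (default
#'   `TRUE`).
#' @return A `cv_result`: pooled `predictions` tibble, per-fold chosen
#'   parameters, per-repetition and summary MCC/AUC, and the no-leakage
#'   check outcome.
#' @export
nested_cv <- function(method, ds, grid = NULL,
                      protocol = c("lopo", "kfold3", "kfold3_naive"),
                      repetitions = 1L, seed = 1L, inner_k = 3L,
                      n_draws = 30L, k = 3L, rescale = TRUE) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(method, "mrsi_method"))
  binary <- length(ds$label_levels) == 2
  all_preds <- list()
  fold_params <- list()
  leakage_ok <- TRUE
  mcc_rep <- numeric(repetitions)
  auc_rep <- rep(NA_real_, repetitions)
  for (r in seq_len(repetitions)) {
    rep_seed <- seed + r - 1L
    plan <- switch(protocol,
      lopo = lopo_folds(ds),
      kfold3 = grouped_kfold(ds, k = k, seed = rep_seed),
      kfold3_naive = voxel_kfold(ds, k = k, seed = rep_seed)
    )
    preds_r <- purrr::map_dfr(seq_len(nrow(plan)), function(f) {
      test_vox <- plan$test_voxels[[f]]
      tr <- subset_voxels(ds, which(!ds$meta$voxel_id %in% test_vox))
      te <- subset_voxels(ds, match(test_vox, ds$meta$voxel_id))
      if (rescale) {
        sc <- fit_rescaler(tr)
        tr <- apply_rescaler(tr, sc)
        te <- apply_rescaler(te, sc)
      }
      search <- rgs_search(method, tr, grid, inner_k = inner_k,
                           n_draws = n_draws,
                           seed = rep_seed * 100L + f)
      if (protocol != "kfold3_naive" &&
          length(intersect(search$patients_seen, plan$test_patients[[f]])) > 0) {
        leakage_ok <<- FALSE
      }
      fit_params <- c(search$params,
                      list(seed = (rep_seed * 1000L + f) %% 100000L))
      model <- method$fit(tr, fit_params)
      out <- method$predict(model, te)
      fold_params[[length(fold_params) + 1L]] <<- tibble::tibble(
        rep = r, fold = f, params = list(search$params),
        inner_mcc = search$inner_mcc
      )
      out$patient_id <- te$meta$patient_id[match(out$voxel_id, te$meta$voxel_id)]
      out$truth <- te$meta$label[match(out$voxel_id, te$meta$voxel_id)]
      out$rep <- r
      out$fold <- f
      out
    })
    mcc_rep[r] <- if (binary) mcc(preds_r$truth, preds_r$predicted) else NA_real_
    if (binary) {
      pos <- ds$label_levels[2]
      score_col <- paste0("score_", pos)
      if (score_col %in% names(preds_r)) {
        auc_rep[r] <- roc_auc(preds_r$truth, preds_r[[score_col]], positive = pos)$auc
      }
    }
    all_preds[[r]] <- preds_r
  }
  predictions <- dplyr::relocate(dplyr::bind_rows(all_preds),
                                 "rep", "fold", "voxel_id", "patient_id",
                                 "truth", "predicted")
  structure(
    list(
      predictions = predictions,
      fold_params = dplyr::bind_rows(fold_params),
      mcc = mcc_rep, mcc_mean = mean(mcc_rep), mcc_sd = sd(mcc_rep),
      auc = auc_rep,
      protocol = protocol, method = method$name,
      label_levels = ds$label_levels,
      leakage_ok = leakage_ok, repetitions = repetitions, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, protocol %s, %d repetition(s)\n",
              x$method, x$protocol, x$repetitions))
  cat(sprintf("  MCC %.4f (sd %s)\n", x$mcc_mean,
              ifelse(is.na(x$mcc_sd), "NA", sprintf("%.4f", x$mcc_sd))))
  if (any(!is.na(x$auc))) {
    cat(sprintf("  AUC %.4f\n", mean(x$auc, na.rm = TRUE)))
  }
  if (!x$leakage_ok) cat("  WARNING: hyper-parameter search touched test patients\n")
  invisible(x)
}

#' @exportS3Method tidy cv_result
#' @describeIn nested_cv Pooled out-of-fold predictions as a tibble.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @exportS3Method glance cv_result
#' @describeIn nested_cv One-row summary (method, protocol, MCC mean/sd,
#'   AUC mean).
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, protocol = x$protocol, repetitions = x$repetitions,
    mcc_mean = x$mcc_mean, mcc_sd = x$mcc_sd,
    auc_mean = mean(x$auc, na.rm = TRUE),
    leakage_ok = x$leakage_ok
  )
}

#' @exportS3Method autoplot cv_result
#' @describeIn nested_cv Pooled ROC curves, one per repetition (binary
#'   tasks with scores).
#' @param object A `cv_result`.
#' @export
autoplot.cv_result <- function(object, ...) {
  pos <- object$label_levels[2]
  score_col <- paste0("score_", pos)
  if (!score_col %in% names(object$predictions)) {
    abort("no score column available for ROC curves")
  }
  curves <- dplyr::group_modify(
    dplyr::group_by(object$predictions, .data$rep),
    function(df, key) roc_auc(df$truth, df[[score_col]], positive = pos)$curve
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = factor(.data$rep))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "repetition") +
    ggplot2::theme_minimal()
}
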