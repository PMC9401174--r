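#' Convolutional-layer features of every voxel
#'
#' The post-activation merged feature matrix (spectral branch first), i.e.
#' the representation seen by the output layer. This is the input to the
#' stability-selection retraining.
#'
#' @param model A trained `slcnn`.
#' @param ds An `mrsi_dataset` with matching shapes.
#' @return Numeric matrix `n_voxels x merged_features`, voxel ids as row
#'   names; column `f + 1` is merged feature `f` of [feature_index_map()].
#' @export
conv_features <- function(model, ds) {
  design <- slcnn_design(ds, model$config, model$dims)
  Phi <- slcnn_forward(model, design)$Phi
  rownames(Phi) <- ds$meta$voxel_id
  Phi
}

#' Refit the output layer as a sparse logistic model
#'
#' The network's last layer is a softmax over the convolutional features,
#' i.e. a (multinomial) logistic regression. Refitting it on a data subset
#' with a sparsity-inducing penalty gives exactly-zero coefficients for
#' irrelevant features — the per-resample selector used by
#' [stability_selection()]. The penalty is an elastic net: the L1 part
#' zeroes out irrelevant features, while the ridge part distributes weight
#' across groups of correlated features (neighboring convolutional
#' positions are highly correlated), so a whole signal-carrying group is
#' selected together instead of a single arbitrary representative per
#' resample.
#'
#' @param features Numeric matrix `n x d` of convolutional features.
#' @param labels Class labels, length `n`, at least two classes present.
#' @param penalty_strength Penalty weight on the summed log-likelihood
#'   scale (the glmnet `lambda` is `penalty_strength / n`); default 1.
#' @param alpha Elastic-net mixing in `[0, 1]`: 1 is pure lasso, 0 pure
#'   ridge; default 0.5.
#' @param standardize Standardize features inside the fit (default `TRUE`).
#' @return A `d x n_classes` coefficient matrix (single column for binary
#'   tasks: coefficients toward the positive class, the *second* factor
#'   level).
#' @export
retrain_last_layer <- function(features, labels, penalty_strength = 1,
                               alpha = 0.5, standardize = TRUE) {
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) < 2) abort("labels must contain at least two classes")
  n <- nrow(features)
  if (all(apply(features, 2, stats::var) == 0)) {
    # nothing to select from constant features
    co <- matrix(0, ncol(features), if (nlevels(y) == 2) 1 else nlevels(y))
    rownames(co) <- colnames(features)
    colnames(co) <- if (nlevels(y) == 2) levels(y)[2] else levels(y)
    return(co)
  }
  lam <- penalty_strength / n
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  # glmnet warns about small per-class counts on resampled subsets; the
  # subsample sizes are part of the stability-selection design
  fit <- suppressWarnings(
    glmnet::glmnet(features, y, family = fam, alpha = alpha,
                   lambda = lam, standardize = standardize)
  )
  if (fam == "binomial") {
    co <- as.matrix(stats::coef(fit))[-1, , drop = FALSE]
    colnames(co) <- levels(y)[2]
  } else {
    co <- do.call(cbind, purrr::map(stats::coef(fit), function(m) {
      as.matrix(m)[-1, , drop = FALSE]
    }))
    colnames(co) <- levels(y)
  }
  rownames(co) <- colnames(features)
  co
}

#' Stability selection over convolutional features
#'
#' Repeats sparse output-layer retraining on `B` random subsets of the data
#' (a fraction of the *patients*, drawn without replacement, stratified by
#' class — a patient's voxels never split across in/out of a subsample) and
#' records, per merged feature, the fraction of resamples in which its
#' coefficient was positive toward some class. Features recurring at high
#' frequency under a conservative threshold (0.96 by default downstream)
#' are the diagnostically relevant ones.
#'
#' @param model A trained `slcnn`.
#' @param ds The dataset (same schema the model was trained on).
#' @param B Number of resamples (frequencies are multiples of `1/B`).
#' @param fraction Fraction of patients per class in each subsample, in
#'   (0, 1).
#' @param penalty_strength,alpha Passed to [retrain_last_layer()].
#' @param seed Seed for the resampling stream.
#' @return A `relevance_profile`: the [feature_index_map()] tibble plus a
#'   `frequency` column, with attributes `B`, `fraction`, `n_skipped`
#'   (resamples whose subset contained one class) and the model geometry.
#' @export
stability_selection <- function(model, ds, B = 100L, fraction = 0.5,
                                penalty_strength = 1, alpha = 0.5,
                                seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must lie in (0, 1)")
  if (B < 1) abort("B must be >= 1")
  Phi <- conv_features(model, ds)
  colnames(Phi) <- paste0("f", seq_len(ncol(Phi)) - 1L)
  pat <- dplyr::distinct(ds$meta, .data$patient_id, .data$label)
  pat_split <- split(pat$patient_id, pat$label)
  counts <- rep(0L, ncol(Phi))
  n_skipped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      take <- unlist(purrr::map(pat_split, function(p) {
        k <- max(1L, floor(fraction * length(p)))
        sample(p, k)
      }), use.names = FALSE)
      idx <- which(ds$meta$patient_id %in% take)
      sub_labels <- ds$meta$label[idx]
      if (length(unique(sub_labels)) < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      co <- retrain_last_layer(Phi[idx, , drop = FALSE],
                               factor(sub_labels, levels = model$label_levels),
                               penalty_strength = penalty_strength,
                               alpha = alpha)
      selected <- apply(co > 0, 1, any)
      counts <- counts + as.integer(selected)
    }
  })
  out <- feature_index_map(model)
  out$frequency <- counts / B
  structure(out,
            class = c("relevance_profile", class(out)),
            B = as.integer(B), fraction = fraction,
            n_skipped = n_skipped, seed = as.integer(seed),
            channels = model$dims$C,
            channel_names = model$channel_names %||% model$dims$channel_names)
}

#' Select features above the stability threshold
#'
#' @param profile A `relevance_profile`.
#' @param threshold Selection-frequency threshold in (0, 1]; 0.96 is the
#'   conservative default used throughout.
#' @return The profile rows with `frequency >= threshold` (possibly none).
#' @export
select_features <- function(profile, threshold = 0.96) {
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  dplyr::filter(tibble::as_tibble(profile), .data$frequency >= threshold)
}

#' Map a spectral feature back to its input region
#'
#' Deconvolution of the index arithmetic: convolutional output position `j`
#' at stride `s` and kernel size `N` is fed by input bins
#' `[j * s, j * s + N - 1]` (0-based, inclusive), independent of the kernel
#' identity. Because spectral kernels sum over channels, the receptive
#' field covers that interval in *every* channel; one region row per
#' channel is returned.
#'
#' @param feature_index 0-based merged feature index; must belong to the
#'   spectral branch.
#' @param model The `slcnn` defining the geometry.
#' @param ppm_axis Optional ppm axis of length `P` used to attach
#'   `ppm_start`/`ppm_end` bounds.
#' @return A tibble with columns `channel` (1-based), `start_bin`,
#'   `end_bin` (0-based inclusive), `ppm_start`, `ppm_end`, `features`
#'   (list of source feature indices).
#' @export
map_feature_to_region <- function(feature_index, model, ppm_axis = NULL) {
  fmap <- feature_index_map(model)
  row <- fmap[fmap$feature == feature_index, ]
  if (nrow(row) != 1) abort(sprintf("unknown feature index %s", feature_index))
  if (row$branch != "spectral") {
    abort("image-branch features have no spectral region; mapping is spectra-only")
  }
  out <- tibble::tibble(
    channel = seq_len(model$dims$C),
    start_bin = row$start_bin,
    end_bin = row$end_bin,
    features = list(as.integer(feature_index))
  )
  attach_ppm(out, ppm_axis)
}

attach_ppm <- function(regions, ppm_axis) {
  if (is.null(ppm_axis)) {
    regions$ppm_start <- NA_real_
    regions$ppm_end <- NA_real_
  } else {
    regions$ppm_start <- ppm_axis[regions$start_bin + 1L]
    regions$ppm_end <- ppm_axis[regions$end_bin + 1L]
  }
  regions
}

#' Merge overlapping or adjacent spectral regions
#'
#' Within each channel, intervals that overlap or touch (gap 0) are merged
#' into maximal intervals; source feature indices are unioned and the
#' maximum stability frequency is carried when present.
#'
#' @param regions A tibble of regions (`channel`, `start_bin`, `end_bin`,
#'   optional `features` list-column and `max_frequency`).
#' @return Merged regions sorted by channel and `start_bin`.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions)
  if (!"features" %in% names(regions)) {
    regions$features <- purrr::map(seq_len(nrow(regions)), ~ integer())
  }
  has_freq <- "max_frequency" %in% names(regions)
  out <- list()
  for (ch in sort(unique(regions$channel))) {
    sub <- dplyr::arrange(regions[regions$channel == ch, ], .data$start_bin)
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      nxt <- sub[i, ]
      if (nxt$start_bin <= cur$end_bin + 1L) {
        cur$end_bin <- max(cur$end_bin, nxt$end_bin)
        cur$features <- list(sort(union(cur$features[[1]], nxt$features[[1]])))
        if (has_freq) cur$max_frequency <- max(cur$max_frequency, nxt$max_frequency)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  dplyr::bind_rows(out)
}

#' Selected spectral regions of a stability profile
#'
#' Convenience wrapper: thresholds the profile, maps every selected
#' spectral feature to its receptive field, and merges the intervals per
#' channel.
#'
#' @param profile A `relevance_profile`.
#' @param model The `slcnn` the profile was computed on.
#' @param threshold Selection threshold (default 0.96).
#' @param ppm_axis Optional ppm axis for ppm bounds.
#' @return A merged-region tibble with `n_features` and `max_frequency`
#'   columns (zero rows when nothing passes the threshold).
#' @export
relevance_regions <- function(profile, model, threshold = 0.96,
                              ppm_axis = NULL) {
  sel <- select_features(profile, threshold)
  sel <- sel[sel$branch == "spectral", ]
  if (nrow(sel) == 0) {
    return(tibble::tibble(
      channel = integer(), start_bin = integer(), end_bin = integer(),
      ppm_start = numeric(), ppm_end = numeric(),
      n_features = integer(), max_frequency = numeric()
    ))
  }
  regions <- purrr::pmap_dfr(
    list(sel$feature, sel$frequency),
    function(f, fr) {
      r <- map_feature_to_region(f, model, ppm_axis)
      r$max_frequency <- fr
      r
    }
  )
  merged <- merge_regions(regions)
  merged$n_features <- lengths(merged$features)
  merged <- attach_ppm(dplyr::select(merged, -dplyr::any_of(c("ppm_start", "ppm_end"))),
                       ppm_axis)
  dplyr::select(merged, "channel", "start_bin", "end_bin",
                "ppm_start", "ppm_end", "n_features", "max_frequency")
}

#' @export
print.relevance_profile <- function(x, ...) {
  B <- attr(x, "B")
  cat(sprintf("<relevance_profile> %d features, B = %d, fraction = %.2f\n",
              nrow(x), B, attr(x, "fraction")))
  if (attr(x, "n_skipped") > 0) {
    cat(sprintf("  %d resample(s) skipped (single-class subset)\n",
                attr(x, "n_skipped")))
  }
  NextMethod()
}

#' @exportS3Method autoplot relevance_profile
#' Plot a stability-selection profile
#'
#' Selection frequency of every spectral feature against the center of its
#' receptive field, one panel per kernel, with the threshold drawn as a
#' horizontal line.
#'
#' @param object A `relevance_profile`.
#' @param threshold Threshold line position (default 0.96).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relevance_profile <- function(object, threshold = 0.96, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$branch == "spectral")
  df$center <- (df$start_bin + df$end_bin) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$frequency)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~kernel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "receptive-field center (bin)",
                  y = "selection frequency") +
    ggplot2::theme_minimal()
}
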