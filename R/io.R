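#' Write an MRSI dataset to a directory
#'
#' On-disk layout: a YAML `manifest.yaml` naming a `metadata.csv`
#' (`voxel_id,patient_id,roi_id,label`), a `spectra.csv` numeric matrix with
#' one row per voxel and `channels * P` columns (channel-major), an optional
#' `ppm_axis.csv`, and one `images_<contrast>.csv` per MRI contrast with
#' `H * W` columns (column-major flattening). Array shapes are recorded in
#' the manifest; row `i` of every file corresponds to row `i` of the
#' metadata.
#'
#' @param ds An `mrsi_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [load_dataset()]
#' @export
write_dataset <- function(ds, dir) {
  validate_mrsi_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ds$meta, file.path(dir, "metadata.csv"), progress = FALSE)
  dm <- dim(ds$spectra)
  sp <- concatenate_modalities(ds, "spectra")
  sp_df <- tibble::as_tibble(sp, .name_repair = "minimal")
  names(sp_df) <- paste0("s", seq_len(ncol(sp)))
  readr::write_csv(sp_df, file.path(dir, "spectra.csv"), progress = FALSE)
  manifest <- list(
    format = "mrsiclass-dataset-v1",
    metadata = "metadata.csv",
    spectra = list(file = "spectra.csv", channels = dm[2], P = dm[3]),
    label_levels = as.list(ds$label_levels)
  )
  if (!is.null(ds$channel_names)) {
    manifest$spectra$channel_names <- as.list(ds$channel_names)
  }
  if (!is.null(ds$ppm_axis)) {
    readr::write_csv(tibble::tibble(ppm = ds$ppm_axis),
                     file.path(dir, "ppm_axis.csv"), progress = FALSE)
    manifest$ppm_axis <- "ppm_axis.csv"
  }
  if (length(ds$images) > 0) {
    manifest$images <- purrr::imap(ds$images, function(arr, ct) {
      d <- dim(arr)
      fn <- paste0("images_", ct, ".csv")
      df <- tibble::as_tibble(matrix(arr, nrow = d[1]), .name_repair = "minimal")
      names(df) <- paste0("px", seq_len(ncol(df)))
      readr::write_csv(df, file.path(dir, fn), progress = FALSE)
      list(file = fn, H = d[2], W = d[3])
    })
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load an MRSI dataset from a manifest directory
#'
#' Reads the layout written by [write_dataset()] and re-validates every
#' dataset invariant. Errors name the missing file or the first offending
#' voxel.
#'
#' @param dir Directory containing `manifest.yaml`, or a path to the
#'   manifest itself.
#' @return A validated `mrsi_dataset`; metadata row order is preserved.
#' @export
load_dataset <- function(dir) {
  manifest_path <- if (grepl("\\.ya?ml$", dir)) dir else file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  root <- dirname(manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  need <- function(fn) {
    path <- file.path(root, fn)
    if (!file.exists(path)) abort(sprintf("dataset file not found: %s", path))
    path
  }
  meta <- readr::read_csv(need(manifest$metadata), show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  sp_raw <- readr::read_csv(need(manifest$spectra$file), show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_double()))
  channels <- as.integer(manifest$spectra$channels)
  P <- as.integer(manifest$spectra$P)
  if (nrow(sp_raw) != nrow(meta)) {
    abort(sprintf("spectra file has %d rows but metadata has %d voxels",
                  nrow(sp_raw), nrow(meta)))
  }
  if (ncol(sp_raw) != channels * P) {
    abort(sprintf("spectra file has %d columns, expected channels * P = %d",
                  ncol(sp_raw), channels * P))
  }
  spectra <- array(0, dim = c(nrow(meta), channels, P))
  m <- as.matrix(sp_raw)
  for (ch in seq_len(channels)) {
    spectra[, ch, ] <- m[, (ch - 1L) * P + seq_len(P), drop = FALSE]
  }
  ppm <- NULL
  if (!is.null(manifest$ppm_axis)) {
    ppm <- readr::read_csv(need(manifest$ppm_axis), show_col_types = FALSE,
                           col_types = "d")$ppm
  }
  images <- list()
  if (!is.null(manifest$images)) {
    images <- purrr::imap(manifest$images, function(info, ct) {
      df <- readr::read_csv(need(info$file), show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_double()))
      if (nrow(df) != nrow(meta)) {
        abort(sprintf("image file for contrast '%s' has %d rows, expected %d",
                      ct, nrow(df), nrow(meta)))
      }
      array(as.matrix(df), dim = c(nrow(meta), as.integer(info$H), as.integer(info$W)))
    })
  }
  mrsi_dataset(
    meta = meta, spectra = spectra, images = images, ppm_axis = ppm,
    label_levels = as.character(unlist(manifest$label_levels)),
    channel_names = if (!is.null(manifest$spectra$channel_names)) {
      as.character(unlist(manifest$spectra$channel_names))
    }
  )
}

#' Fit a unit-interval rescaler on a training subset
#'
#' Computes per-feature minimum and range (per frequency bin and channel for
#' spectra; per pixel position and contrast for images) using only the
#' voxels named in `fit_ids`. Fitting on the training split of each
#' cross-validation fold and applying to the held-out split keeps the
#' rescaling leakage-free.
#'
#' @param ds An `mrsi_dataset`.
#' @param fit_ids Character vector of voxel ids to fit on (typically the
#'   training split). Must be non-empty and a subset of the dataset.
#' @return An object of class `mrsi_rescaler` holding per-stream min/range
#'   arrays.
#' @seealso [apply_rescaler()]
#' @export
fit_rescaler <- function(ds, fit_ids = ds$meta$voxel_id) {
  if (length(fit_ids) == 0) abort("fit_ids must be non-empty")
  idx <- match(fit_ids, ds$meta$voxel_id)
  if (anyNA(idx)) abort("fit_ids contains voxel ids not in the dataset")
  sub <- ds$spectra[idx, , , drop = FALSE]
  spec_min <- apply(sub, c(2, 3), min)
  spec_rng <- apply(sub, c(2, 3), max) - spec_min
  img <- purrr::map(ds$images, function(arr) {
    s <- arr[idx, , , drop = FALSE]
    mn <- apply(s, c(2, 3), min)
    list(min = mn, range = apply(s, c(2, 3), max) - mn)
  })
  structure(
    list(
      spectra = list(min = spec_min, range = spec_rng),
      images = img,
      spec_dim = dim(ds$spectra)[-1]
    ),
    class = "mrsi_rescaler"
  )
}

#' Apply a fitted unit-interval rescaler
#'
#' Transforms every feature as `(x - min) / range` with the parameters from
#' [fit_rescaler()]. Features that were constant in the fit subset
#' (range 0) map to 0. Values outside the fitted range are *not* clipped, so
#' held-out voxels may fall outside `[0, 1]`.
#'
#' @param ds An `mrsi_dataset`.
#' @param params An `mrsi_rescaler` fitted on a compatible dataset shape.
#' @return A rescaled `mrsi_dataset`.
#' @export
apply_rescaler <- function(ds, params) {
  stopifnot(inherits(params, "mrsi_rescaler"))
  if (!identical(dim(ds$spectra)[-1], as.integer(params$spec_dim)) &&
      !identical(dim(ds$spectra)[-1], params$spec_dim)) {
    abort("rescaler was fitted on a different spectra shape")
  }
  if (!identical(sort(names(ds$images)), sort(names(params$images)))) {
    abort("rescaler was fitted on a different set of image contrasts")
  }
  out <- ds
  n <- n_voxels(ds)
  rescale_arr <- function(arr, mn, rng) {
    denom <- ifelse(rng > 0, rng, 1)
    res <- sweep(arr, c(2, 3), mn, "-")
    res <- sweep(res, c(2, 3), denom, "/")
    if (any(rng == 0)) {
      zero <- which(rng == 0, arr.ind = TRUE)
      for (r in seq_len(nrow(zero))) {
        res[, zero[r, 1], zero[r, 2]] <- 0
      }
    }
    res
  }
  out$spectra <- rescale_arr(ds$spectra, params$spectra$min, params$spectra$range)
  out$images <- purrr::imap(ds$images, function(arr, ct) {
    if (!identical(dim(arr)[-1], dim(params$images[[ct]]$min))) {
      abort(sprintf("rescaler shape mismatch for contrast '%s'", ct))
    }
    rescale_arr(arr, params$images[[ct]]$min, params$images[[ct]]$range)
  })
  validate_mrsi_dataset(out)
  out
}

#' Export per-voxel predictions as CSV
#'
#' Writes `voxel_id,patient_id,true_label,predicted_label,score_<class>...`,
#' the interchange format used by the evaluation harness.
#'
#' @param predictions A tibble as produced by [nested_cv()] (columns
#'   `voxel_id`, `patient_id`, `truth`, `predicted` and one `score_<class>`
#'   column per class).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- dplyr::rename(predictions,
                       true_label = "truth", predicted_label = "predicted")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
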