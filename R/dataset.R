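#' Build an in-memory MRSI voxel dataset
#'
#' The central data container of the package: one row of `meta` per brain
#' voxel, a spectra array holding one (possibly multi-channel) metabolite
#' spectrum per voxel, and zero or more co-registered image-patch arrays,
#' one per MRI contrast (e.g. T1, T2, PD, Gd).
#'
#' @param meta A data frame with columns `voxel_id`, `patient_id`, `roi_id`
#'   (may be `NA`) and `label`. One row per voxel; row order is preserved and
#'   defines the array row order.
#' @param spectra Numeric array of dimension `n_voxels x channels x P`, or a
#'   matrix `n_voxels x P` for single-channel data (promoted to 3-d).
#' @param images Named list of numeric arrays, each `n_voxels x H x W`. The
#'   list order defines the contrast order used when modalities are
#'   concatenated. May be empty.
#' @param ppm_axis Optional numeric vector of length `P` giving the chemical
#'   shift of every frequency bin; must be strictly monotonic (conventionally
#'   stored descending for MR spectra).
#' @param label_levels Ordered class vocabulary. Defaults to the sorted
#'   unique labels present. For binary tasks the second level is treated as
#'   the positive class throughout the package.
#' @param channel_names Optional names for the spectral channels (e.g. ROI
#'   names when several single-voxel regions are stacked as channels).
#'
#' @return An object of class `mrsi_dataset`: a list with elements `meta`
#'   (tibble), `spectra`, `images`, `ppm_axis`, `label_levels`,
#'   `channel_names`.
#' @examples
#' meta <- tibble::tibble(
#'   voxel_id = c("v1", "v2"), patient_id = c("p1", "p2"),
#'   roi_id = NA_character_, label = c("a", "b")
#' )
#' ds <- mrsi_dataset(meta, matrix(rnorm(20), nrow = 2))
#' n_voxels(ds)
#' @export
mrsi_dataset <- function(meta, spectra, images = list(), ppm_axis = NULL,
                         label_levels = NULL, channel_names = NULL) {
  meta <- tibble::as_tibble(meta)
  required <- c("voxel_id", "patient_id", "label")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("meta is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"roi_id" %in% names(meta)) meta$roi_id <- NA_character_
  meta <- dplyr::mutate(meta, dplyr::across(
    c("voxel_id", "patient_id", "roi_id", "label"), as.character
  ))
  if (is.matrix(spectra)) {
    spectra <- array(spectra, dim = c(nrow(spectra), 1L, ncol(spectra)))
  }
  if (is.null(label_levels)) label_levels <- sort(unique(meta$label))
  ds <- structure(
    list(
      meta = meta[, c("voxel_id", "patient_id", "roi_id", "label")],
      spectra = spectra,
      images = images,
      ppm_axis = ppm_axis,
      label_levels = label_levels,
      channel_names = channel_names
    ),
    class = "mrsi_dataset"
  )
  validate_mrsi_dataset(ds)
  ds
}

#' Validate an MRSI dataset's structural invariants
#'
#' Checks that all spectra share one `(channels, P)` shape, that image arrays
#' match the voxel count, that intensities are finite, that labels belong to
#' the vocabulary and voxel ids are unique. Called by [mrsi_dataset()]; useful
#' directly after manual surgery on a dataset.
#'
#' @param ds An `mrsi_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error naming the offending
#'   voxel or contrast.
#' @export
validate_mrsi_dataset <- function(ds) {
  stopifnot(inherits(ds, "mrsi_dataset"))
  n <- nrow(ds$meta)
  if (length(dim(ds$spectra)) != 3L) {
    abort("spectra must be an n_voxels x channels x P array")
  }
  if (dim(ds$spectra)[1] != n) {
    abort(sprintf(
      "spectra has %d rows but metadata has %d voxels", dim(ds$spectra)[1], n
    ))
  }
  if (!all(is.finite(ds$spectra))) {
    bad <- which(apply(ds$spectra, 1, function(x) !all(is.finite(x))))[1]
    abort(sprintf("non-finite spectrum intensities for voxel_id '%s'",
                  ds$meta$voxel_id[bad]))
  }
  if (anyDuplicated(ds$meta$voxel_id)) abort("duplicated voxel_id in metadata")
  if (any(!nzchar(ds$meta$patient_id) | is.na(ds$meta$patient_id))) {
    abort("patient_id must be non-empty for every voxel")
  }
  unknown <- setdiff(unique(ds$meta$label), ds$label_levels)
  if (length(unknown) > 0) {
    abort(paste0("label(s) outside the vocabulary: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(ds$ppm_axis)) {
    if (length(ds$ppm_axis) != dim(ds$spectra)[3]) {
      abort("ppm_axis length must equal the number of frequency bins")
    }
    d <- diff(ds$ppm_axis)
    if (!(all(d > 0) || all(d < 0))) abort("ppm_axis must be strictly monotonic")
  }
  if (!is.null(ds$channel_names) &&
      length(ds$channel_names) != dim(ds$spectra)[2]) {
    abort("channel_names length must equal the number of channels")
  }
  if (length(ds$images) > 0) {
    if (is.null(names(ds$images)) || any(!nzchar(names(ds$images)))) {
      abort("images must be a named list (one name per contrast)")
    }
    for (contrast in names(ds$images)) {
      arr <- ds$images[[contrast]]
      if (length(dim(arr)) != 3L || dim(arr)[1] != n) {
        abort(sprintf("image array '%s' must have dimension n_voxels x H x W", contrast))
      }
      if (!all(is.finite(arr))) {
        bad <- which(apply(arr, 1, function(x) !all(is.finite(x))))[1]
        abort(sprintf("non-finite pixels in contrast '%s' for voxel_id '%s'",
                      contrast, ds$meta$voxel_id[bad]))
      }
    }
  }
  invisible(ds)
}

#' @export
print.mrsi_dataset <- function(x, ...) {
  dm <- dim(x$spectra)
  cat(sprintf(
    "<mrsi_dataset> %d voxels, %d patients, %d classes\n",
    dm[1], dplyr::n_distinct(x$meta$patient_id), length(x$label_levels)
  ))
  cat(sprintf("  spectra: %d channel(s) x %d bins\n", dm[2], dm[3]))
  if (length(x$images) > 0) {
    for (ct in names(x$images)) {
      d <- dim(x$images[[ct]])
      cat(sprintf("  images[%s]: %d x %d patches\n", ct, d[2], d[3]))
    }
  }
  cat(sprintf("  labels: %s\n", paste(x$label_levels, collapse = ", ")))
  invisible(x)
}

#' Number of voxels in a dataset
#' @param ds An `mrsi_dataset`.
#' @return Integer count.
#' @export
n_voxels <- function(ds) nrow(ds$meta)

#' Patient identifiers of a dataset
#' @param ds An `mrsi_dataset`.
#' @return Character vector of unique patient ids, in first-appearance order.
#' @export
patient_ids <- function(ds) unique(ds$meta$patient_id)

#' Subset a dataset by voxel
#'
#' @param ds An `mrsi_dataset`.
#' @param idx Integer/logical row index, or a character vector of voxel ids.
#' @return A new `mrsi_dataset` with the selected voxels, order following
#'   `idx`.
#' @export
subset_voxels <- function(ds, idx) {
  if (is.character(idx)) {
    idx <- match(idx, ds$meta$voxel_id)
    if (anyNA(idx)) abort("unknown voxel_id in subset request")
  }
  images <- purrr::map(ds$images, function(a) a[idx, , , drop = FALSE])
  out <- ds
  out$meta <- ds$meta[idx, ]
  out$spectra <- ds$spectra[idx, , , drop = FALSE]
  out$images <- images
  validate_mrsi_dataset(out)
  out
}

#' Row-bind two voxel datasets
#'
#' Used, e.g., to pool simulated cohorts whose class signal lives in
#' different modalities into one "complementary signal" dataset. Shapes,
#' contrast sets and label vocabularies must agree.
#'
#' @param a,b `mrsi_dataset` objects with identical modality shapes.
#' @return The combined `mrsi_dataset`.
#' @export
bind_datasets <- function(a, b) {
  if (!identical(dim(a$spectra)[-1], dim(b$spectra)[-1])) {
    abort("spectra shapes differ between datasets")
  }
  if (!identical(names(a$images), names(b$images))) {
    abort("image contrast sets differ between datasets")
  }
  images <- purrr::imap(a$images, function(arr, ct) {
    if (!identical(dim(arr)[-1], dim(b$images[[ct]])[-1])) {
      abort(sprintf("image shapes differ for contrast '%s'", ct))
    }
    abind3(arr, b$images[[ct]])
  })
  mrsi_dataset(
    meta = dplyr::bind_rows(a$meta, b$meta),
    spectra = abind3(a$spectra, b$spectra),
    images = images,
    ppm_axis = a$ppm_axis,
    label_levels = union(a$label_levels, b$label_levels),
    channel_names = a$channel_names
  )
}

# bind two n x d1 x d2 arrays along the first margin
abind3 <- function(x, y) {
  out <- array(0, dim = c(dim(x)[1] + dim(y)[1], dim(x)[2], dim(x)[3]))
  out[seq_len(dim(x)[1]), , ] <- x
  out[dim(x)[1] + seq_len(dim(y)[1]), , ] <- y
  out
}

#' Flatten all modalities of each voxel into one feature vector
#'
#' Concatenates, per voxel, the flattened spectrum channels (channel 1 bins
#' first, then channel 2, ...) followed by the flattened image patches in the
#' dataset's declared contrast order. This is the representation used by the
#' SVM baseline ("images and spectra concatenated into a unique sample") and
#' by the PLS family.
#'
#' @param ds An `mrsi_dataset`.
#' @param modalities Which streams to include: `"all"` (default),
#'   `"spectra"`, or `"images"`.
#' @return Numeric matrix `n_voxels x (channels * P + sum(H * W))` with
#'   voxel ids as row names; column order is deterministic.
#' @export
concatenate_modalities <- function(ds, modalities = c("all", "spectra", "images")) {
  modalities <- match.arg(modalities)
  parts <- list()
  if (modalities %in% c("all", "spectra")) {
    dm <- dim(ds$spectra)
    # channel-major flattening: columns are (channel 1, bins 1..P), (channel 2, ...)
    sp <- matrix(0, nrow = dm[1], ncol = dm[2] * dm[3])
    for (ch in seq_len(dm[2])) {
      sp[, (ch - 1L) * dm[3] + seq_len(dm[3])] <- ds$spectra[, ch, ]
    }
    parts <- c(parts, list(sp))
  }
  if (modalities %in% c("all", "images") && length(ds$images) > 0) {
    for (ct in names(ds$images)) {
      arr <- ds$images[[ct]]
      d <- dim(arr)
      parts <- c(parts, list(matrix(arr, nrow = d[1])))
    }
  }
  if (length(parts) == 0) abort("no modality selected or present")
  out <- do.call(cbind, parts)
  rownames(out) <- ds$meta$voxel_id
  out
}

#' Stack per-ROI single-voxel spectra as channels
#'
#' For cohorts where each subject contributes one spectrum per brain region
#' of interest, the per-region spectra can be combined "as if they were
#' different channels" of a single multi-channel spectrum.
#'
#' @param per_roi Named list mapping `roi_id` to a single-channel spectrum
#'   (numeric vector of length `P`, or a `1 x P` matrix).
#' @param roi_order Character vector giving the channel order; every entry
#'   must be present in `per_roi`.
#' @param subject_id Optional subject identifier used in error messages.
#' @return A `channels x P` matrix with `rownames = roi_order`.
#' @examples
#' s <- stack_roi_channels(
#'   list(ACC = rnorm(16), RSC = rnorm(16)), c("ACC", "RSC")
#' )
#' dim(s)
#' @export
stack_roi_channels <- function(per_roi, roi_order, subject_id = NULL) {
  missing_roi <- setdiff(roi_order, names(per_roi))
  if (length(missing_roi) > 0) {
    who <- if (is.null(subject_id)) "subject" else paste0("subject '", subject_id, "'")
    abort(sprintf("%s is missing ROI(s): %s", who, paste(missing_roi, collapse = ", ")))
  }
  rows <- purrr::map(roi_order, function(r) {
    x <- per_roi[[r]]
    if (is.matrix(x)) {
      if (nrow(x) != 1L) abort(sprintf("ROI '%s' spectrum must be single-channel", r))
      x <- x[1, ]
    }
    as.numeric(x)
  })
  p <- unique(lengths(rows))
  if (length(p) != 1L) abort("all ROI spectra must share one length P")
  out <- do.call(rbind, rows)
  rownames(out) <- roi_order
  out
}

#' Per-voxel metadata with label as factor
#'
#' @param ds An `mrsi_dataset`.
#' @return The metadata tibble with `label` converted to a factor over the
#'   dataset vocabulary (useful for modelling functions).
#' @export
voxel_table <- function(ds) {
  dplyr::mutate(ds$meta, label = factor(.data$label, levels = ds$label_levels))
}
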