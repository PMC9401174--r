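#' Configure a synthetic MRSI cohort
#'
#' Defines the generative model used throughout the test-bed: each voxel
#' spectrum is a sum of Gaussian metabolite peaks whose amplitudes are
#' modulated multiplicatively by (i) a class effect per peak and (ii) a
#' log-normal patient-level random factor shared by all voxels of a patient,
#' plus i.i.d. Gaussian noise per frequency bin. Optional image patches per
#' voxel are Gaussian noise with a class-dependent mean shift.
#'
#' @param P Number of frequency bins per spectrum channel.
#' @param peaks Data frame with columns `name`, `center_bin` (0-based, in
#'   `[0, P-1]`), `width_bins` (Gaussian sigma, > 0), `base_amplitude` (> 0).
#' @param class_effects Named list: class -> named numeric vector of
#'   multiplicative amplitude factors per peak name (missing peaks default
#'   to 1). Class names define the label vocabulary order.
#' @param n_patients_per_class Named integer vector (same classes).
#' @param voxels_per_patient Named integer vector: voxels simulated per
#'   patient of each class.
#' @param patient_effect_sd Standard deviation of the patient random
#'   effects on the log-amplitude scale (>= 0): each patient draws one
#'   independent `exp(N(0, sd^2))` factor per metabolite peak (a
#'   subject-specific metabolite profile), shared by all of the patient's
#'   voxels.
#' @param noise_sd Additive Gaussian noise sd per bin (>= 0), on the scale of
#'   the base amplitudes.
#' @param n_channels Number of stacked spectral channels (e.g. one per brain
#'   ROI); all channels share the same expected peak profile.
#' @param channel_names Optional channel labels, length `n_channels`.
#' @param image_shape `c(H, W)` patch size, or `NULL` for no image branch.
#' @param contrasts Contrast names for the image patches (one array each).
#' @param image_class_effect Named numeric: mean-intensity shift of every
#'   patch for each class (missing classes default to 0).
#' @param image_noise_sd Pixel noise sd.
#' @param image_baseline Baseline mean pixel intensity.
#' @param ppm_range Optional `c(high, low)` chemical-shift bounds; a
#'   descending ppm axis of length `P` is attached to simulated datasets.
#' @param seed Integer seed; all randomness of [simulate_dataset()] flows
#'   from it.
#' @return An object of class `synthetic_config`.
#' @seealso [synthetic_preset()], [simulate_dataset()]
#' @export
synthetic_config <- function(P, peaks, class_effects, n_patients_per_class,
                             voxels_per_patient, patient_effect_sd = 0.25,
                             noise_sd = 0.03, n_channels = 1L,
                             channel_names = NULL, image_shape = NULL,
                             contrasts = "T1", image_class_effect = NULL,
                             image_noise_sd = 1, image_baseline = 0,
                             ppm_range = NULL, seed = 1L) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("name", "center_bin", "width_bins", "base_amplitude") %in% names(peaks)))
  if (any(peaks$center_bin < 0 | peaks$center_bin > P - 1)) {
    abort("peak center_bin must lie in [0, P-1] (0-based)")
  }
  if (any(peaks$width_bins <= 0) || any(peaks$base_amplitude <= 0)) {
    abort("peak widths and base amplitudes must be positive")
  }
  classes <- names(class_effects)
  if (is.null(classes) || length(classes) == 0) abort("class_effects must be a named list")
  if (!setequal(classes, names(n_patients_per_class))) {
    abort("class_effects and n_patients_per_class must name the same classes")
  }
  if (!setequal(classes, names(voxels_per_patient))) {
    abort("class_effects and voxels_per_patient must name the same classes")
  }
  if (patient_effect_sd < 0 || noise_sd < 0 || image_noise_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  if (is.null(image_class_effect)) {
    image_class_effect <- setNames(rep(0, length(classes)), classes)
  }
  structure(
    list(
      P = as.integer(P), peaks = peaks, class_effects = class_effects,
      n_patients_per_class = n_patients_per_class[classes],
      voxels_per_patient = voxels_per_patient[classes],
      patient_effect_sd = patient_effect_sd, noise_sd = noise_sd,
      n_channels = as.integer(n_channels), channel_names = channel_names,
      image_shape = image_shape, contrasts = contrasts,
      image_class_effect = image_class_effect,
      image_noise_sd = image_noise_sd, image_baseline = image_baseline,
      ppm_range = ppm_range, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Load a bundled synthetic cohort preset
#'
#' Two presets ship as YAML config files: `"tumor"`, a proton-MRSI-like
#' cohort (512 bins; Cho/Cr/NAA/Lac peaks; six tissue classes over 29
#' subjects with fewer voxels per patient for higher tumor grades; four
#' image contrasts), and `"alzheimer"`, a phosphorus-MRSI-like cohort (256
#' bins; PCr/Pi/ATP peaks; four single-voxel brain ROIs stacked as channels;
#' 31 + 31 subjects).
#'
#' @param name `"tumor"` or `"alzheimer"`.
#' @param ... Named overrides applied on top of the preset (e.g. `seed`,
#'   `n_patients_per_class`).
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("tumor", "alzheimer"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "mrsiclass", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  raw$peaks <- dplyr::bind_rows(raw$peaks)
  for (fld in c("class_effects")) {
    raw[[fld]] <- purrr::map(raw[[fld]], unlist)
  }
  for (fld in c("n_patients_per_class", "voxels_per_patient", "image_class_effect")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  for (fld in c("image_shape", "ppm_range")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.numeric(unlist(raw[[fld]]))
  }
  for (fld in c("contrasts", "channel_names")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.character(unlist(raw[[fld]]))
  }
  overrides <- list(...)
  cfg_args <- modifyList(raw, overrides)
  do.call(synthetic_config, cfg_args)
}

# analytic (noiseless) class-mean profile, length P; patient_factor may be
# a scalar or one factor per peak (recycled)
expected_profile <- function(config, class_label, patient_factor = 1) {
  eff <- config$class_effects[[class_label]]
  if (is.null(eff)) abort(sprintf("unknown class '%s'", class_label))
  pf <- rep_len(patient_factor, nrow(config$peaks))
  bins <- seq_len(config$P) - 1
  prof <- rep(0, config$P)
  for (i in seq_len(nrow(config$peaks))) {
    pk <- config$peaks[i, ]
    f <- if (pk$name %in% names(eff)) eff[[pk$name]] else 1
    prof <- prof + pk$base_amplitude * f * pf[i] *
      exp(-(bins - pk$center_bin)^2 / (2 * pk$width_bins^2))
  }
  prof
}

#' Expected noiseless spectrum of a class
#'
#' The analytic peak sum for `patient_factor = 1` and no noise; replicated
#' across channels. Useful as an oracle for the generator and for plotting.
#'
#' @param config A `synthetic_config`.
#' @param class_label A class present in the config.
#' @return A `n_channels x P` matrix.
#' @export
expected_spectrum <- function(config, class_label) {
  prof <- expected_profile(config, class_label)
  matrix(prof, nrow = config$n_channels, ncol = config$P, byrow = TRUE)
}

#' Simulate one voxel spectrum
#'
#' Draws noise from the *current* RNG state; [simulate_dataset()] wraps all
#' calls in a single seeded stream.
#'
#' @param config A `synthetic_config`.
#' @param class_label Class to simulate.
#' @param patient_factor Positive multiplicative patient factor(s) applied
#'   to the peak amplitudes: a scalar (global scale) or one factor per
#'   peak (subject-specific metabolite profile).
#' @return A `n_channels x P` intensity matrix.
#' @export
simulate_spectrum <- function(config, class_label, patient_factor = 1) {
  if (any(patient_factor <= 0)) abort("patient_factor must be positive")
  prof <- expected_profile(config, class_label, patient_factor)
  mean_mat <- matrix(prof, nrow = config$n_channels, ncol = config$P,
                     byrow = TRUE)
  noise <- matrix(rnorm(length(mean_mat), sd = config$noise_sd),
                  nrow = nrow(mean_mat))
  mean_mat + noise
}

#' Simulate a full synthetic MRSI cohort
#'
#' Every patient receives one log-normal amplitude factor per peak, shared
#' by all of their voxels (the within-patient similarity that motivates
#' patient-grouped cross-validation); voxel counts follow the per-class
#' configuration; image patches, when configured, are Gaussian noise around
#' a class-shifted mean. All randomness flows from `config$seed`, so
#' regeneration is bit-identical.
#'
#' @param config A `synthetic_config`.
#' @return A validated `mrsi_dataset`.
#' @examples
#' cfg <- synthetic_config(
#'   P = 64,
#'   peaks = tibble::tibble(name = "NAA", center_bin = 30,
#'                          width_bins = 3, base_amplitude = 1),
#'   class_effects = list(a = c(NAA = 1), b = c(NAA = 1.5)),
#'   n_patients_per_class = c(a = 3, b = 3),
#'   voxels_per_patient = c(a = 4, b = 4), seed = 7
#' )
#' ds <- simulate_dataset(cfg)
#' n_voxels(ds)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- names(config$class_effects)
  if (any(config$n_patients_per_class < 2)) {
    warn("some class has < 2 patients; patient-grouped CV will fail on this dataset")
  }
  withr::with_seed(config$seed, {
    rows <- list()
    spectra <- list()
    images <- NULL
    has_img <- !is.null(config$image_shape)
    if (has_img) {
      images <- setNames(vector("list", length(config$contrasts)), config$contrasts)
      for (ct in config$contrasts) images[[ct]] <- list()
    }
    for (cl in classes) {
      n_pat <- config$n_patients_per_class[[cl]]
      n_vox <- config$voxels_per_patient[[cl]]
      img_shift <- if (cl %in% names(config$image_class_effect)) {
        config$image_class_effect[[cl]]
      } else 0
      for (i in seq_len(n_pat)) {
        pid <- sprintf("%s_p%02d", cl, i)
        pf <- exp(rnorm(nrow(config$peaks), 0, config$patient_effect_sd))
        for (v in seq_len(n_vox)) {
          vid <- sprintf("%s_v%03d", pid, v)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            voxel_id = vid, patient_id = pid, roi_id = NA_character_, label = cl
          )
          spectra[[length(spectra) + 1L]] <-
            simulate_spectrum(config, cl, patient_factor = pf)
          if (has_img) {
            H <- config$image_shape[1]; W <- config$image_shape[2]
            for (ct in config$contrasts) {
              images[[ct]][[length(images[[ct]]) + 1L]] <- matrix(
                rnorm(H * W, mean = config$image_baseline + img_shift,
                      sd = config$image_noise_sd), H, W
              )
            }
          }
        }
      }
    }
    meta <- dplyr::bind_rows(rows)
    n <- nrow(meta)
    spec_arr <- array(0, dim = c(n, config$n_channels, config$P))
    for (r in seq_len(n)) spec_arr[r, , ] <- spectra[[r]]
    img_arrs <- list()
    if (has_img) {
      H <- config$image_shape[1]; W <- config$image_shape[2]
      img_arrs <- purrr::map(images, function(lst) {
        arr <- array(0, dim = c(n, H, W))
        for (r in seq_len(n)) arr[r, , ] <- lst[[r]]
        arr
      })
    }
    ppm <- NULL
    if (!is.null(config$ppm_range)) {
      ppm <- seq(config$ppm_range[1], config$ppm_range[2], length.out = config$P)
    }
    mrsi_dataset(meta, spec_arr, images = img_arrs, ppm_axis = ppm,
                 label_levels = classes, channel_names = config$channel_names)
  })
}

#' Simulate a patient-confound null cohort
#'
#' Labels are assigned at the patient level but every class effect is
#' removed (all peak factors 1, image shift 0): the only structure that
#' distinguishes voxels is the patient-specific amplitude factor. A
#' classifier evaluated with voxel-level cross-validation can exploit this
#' patient identity signal; a patient-grouped protocol cannot — the
#' dataset that demonstrates the leakage gap.
#'
#' @param config A `synthetic_config` with `patient_effect_sd > 0` (a value
#'   of 0 removes the confound as well, giving a full null).
#' @return An `mrsi_dataset` with no class signal in expectation.
#' @export
simulate_patient_confound_null <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  null_cfg <- config
  null_cfg$class_effects <- purrr::map(config$class_effects, function(eff) {
    setNames(rep(1, length(eff)), names(eff))
  })
  null_cfg$image_class_effect <- setNames(
    rep(0, length(config$image_class_effect)), names(config$image_class_effect)
  )
  simulate_dataset(null_cfg)
}
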