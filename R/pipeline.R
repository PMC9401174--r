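#' Serialize an SL-CNN model to JSON
#'
#' Plain-text container: named weight arrays with their dimensions, the
#' config, the input geometry and the label vocabulary. Numbers are written
#' at full precision, so save/load round-trips bit-exactly through the
#' decimal representation.
#'
#' @param model A trained `slcnn`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_slcnn <- function(model, path) {
  payload <- list(
    format = "mrsiclass-slcnn-v1",
    config = unclass(model$config),
    input = list(C = model$dims$C, P = model$dims$P,
                 contrasts = model$dims$contrasts,
                 H = model$dims$H, W = model$dims$W),
    label_levels = model$label_levels,
    weights = list(
      W_spec = list(dim = dim(model$W_spec), values = as.vector(model$W_spec)),
      b_spec = model$b_spec,
      V = list(dim = dim(model$V), values = as.vector(model$V)),
      b_out = model$b_out
    ),
    loss_trace = model$loss_trace
  )
  if (isTRUE(model$dims$use_img)) {
    payload$weights$W_img <- list(dim = dim(model$W_img),
                                  values = as.vector(model$W_img))
    payload$weights$b_img <- model$b_img
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an SL-CNN model from JSON
#'
#' @param path A file written by [write_slcnn()].
#' @return An `slcnn` model.
#' @export
read_slcnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mrsiclass-slcnn-v1")) {
    abort("not an mrsiclass SL-CNN model file")
  }
  cfg <- do.call(slcnn_config, p$config[setdiff(names(p$config), character(0))])
  input <- list(C = p$input$C, P = p$input$P)
  if (!is.null(p$weights$W_img)) {
    input$contrasts <- p$input$contrasts
    input$H <- p$input$H
    input$W <- p$input$W
  }
  model <- slcnn_from_weights(
    cfg, input,
    W_spec = matrix(p$weights$W_spec$values, p$weights$W_spec$dim[1]),
    b_spec = p$weights$b_spec,
    V = matrix(p$weights$V$values, p$weights$V$dim[1]),
    b_out = p$weights$b_out,
    W_img = if (!is.null(p$weights$W_img)) {
      matrix(p$weights$W_img$values, p$weights$W_img$dim[1])
    },
    b_img = p$weights$b_img,
    label_levels = p$label_levels
  )
  model$loss_trace <- p$loss_trace
  model
}

#' Simulate, train, evaluate and explain in one deterministic run
#'
#' End-to-end pipeline over the package's stages: generate a synthetic
#' cohort, evaluate the SL-CNN under the chosen grouped protocol, train a
#' final model on all voxels, run stability selection, and write everything
#' as plain-text artifacts. All stages derive their randomness from `seed`,
#' so two runs with the same arguments produce byte-identical files.
#'
#' Artifacts written under `out_dir`: `data/` (dataset layout),
#' `results.csv` (pooled out-of-fold predictions), `summary.json`
#' (MCC/AUC summary and per-repetition values), `model.json` (final
#' trained network) and `regions.csv` (selected spectral regions:
#' `channel,start_bin,end_bin,ppm_start,ppm_end,n_features,max_frequency`).
#'
#' @param out_dir Output directory (created).
#' @param data_config A `synthetic_config`; its seed is replaced by `seed`.
#' @param model_config An `slcnn_config` for both evaluation and the final
#'   model.
#' @param protocol Outer protocol for [nested_cv()].
#' @param grid Optional hyper-parameter grid.
#' @param repetitions CV repetitions.
#' @param B,fraction,threshold Stability-selection controls.
#' @param seed Master seed.
#' @return Invisibly, a list with the dataset, `cv_result`, final model,
#'   relevance profile and region table.
#' @export
run_pipeline <- function(out_dir, data_config, model_config = slcnn_config(),
                         protocol = "lopo", grid = NULL, repetitions = 1L,
                         B = 50L, fraction = 0.5, threshold = 0.96,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_config$seed <- as.integer(seed)
  ds <- simulate_dataset(data_config)
  write_dataset(ds, file.path(out_dir, "data"))
  cv <- nested_cv(method_slcnn(model_config), ds, grid = grid,
                  protocol = protocol, repetitions = repetitions, seed = seed)
  write_predictions(cv$predictions, file.path(out_dir, "results.csv"))
  summary <- list(
    method = cv$method, protocol = cv$protocol,
    repetitions = cv$repetitions,
    mcc_mean = cv$mcc_mean, mcc_sd = cv$mcc_sd,
    mcc_per_rep = cv$mcc, auc_per_rep = cv$auc,
    leakage_ok = cv$leakage_ok
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # final model + relevance map on the full cohort
  sc <- fit_rescaler(ds)
  ds_sc <- apply_rescaler(ds, sc)
  final_cfg <- model_config
  final_cfg$seed <- as.integer(seed)
  model <- slcnn_train(ds_sc, final_cfg)
  write_slcnn(model, file.path(out_dir, "model.json"))
  profile <- stability_selection(model, ds_sc, B = B, fraction = fraction,
                                 seed = seed)
  regions <- relevance_regions(profile, model, threshold = threshold,
                               ppm_axis = ds$ppm_axis)
  readr::write_csv(regions, file.path(out_dir, "regions.csv"), progress = FALSE)
  invisible(list(dataset = ds, cv = cv, model = model,
                 profile = profile, regions = regions))
}
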