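# Run configuration: YAML with full defaults shipped in inst/extdata;
# user files and programmatic overrides merge over the defaults, and every
# command writes the resolved snapshot next to its outputs so a run is
# reproducible from the snapshot + seed alone.

cfg_error <- function(...) {
  stop(structure(class = c("eegadapt_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

data_error <- function(...) {
  stop(structure(class = c("eegadapt_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Starts from the packaged defaults, merges an optional user YAML file,
#' then merges programmatic `overrides`.
#'
#' @param path optional user YAML file.
#' @param overrides optional nested list of overrides.
#' @return A nested configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "eegadapt"))
  if (!is.null(path)) {
    if (!file.exists(path)) cfg_error("config file not found: ", path)
    cfg <- merge_lists(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_lists(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

config_snapshot <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_snapshot.yaml"))
}

synth_spec_from_config <- function(cfg) {
  sc <- cfg$synth
  sig <- lapply(sc$class_signatures, function(w) unlist(w))
  tryCatch(
    synth_spec(n_channels = sc$n_channels, fs = sc$fs,
               duration_s = sc$duration_s, n_recordings = sc$n_recordings,
               class_signatures = sig, artifact_rate = sc$artifact_rate,
               line_noise_hz = sc$line_noise_hz,
               line_noise_amp = sc$line_noise_amp,
               noise_sigma_pct = sc$noise_sigma_pct,
               epoch_window_s = sc$epoch_window_s, seed = sc$seed),
    error = function(e) cfg_error("invalid synth config: ",
                                  conditionMessage(e)))
}

model_config_from_config <- function(cfg, n_classes, n_channels, frame_dim) {
  mc <- cfg$model
  tryCatch(
    model_config(n_classes = n_classes, n_channels = n_channels,
                 seq_len = mc$seq_len, frame_dim = frame_dim,
                 n_layers = mc$n_layers, n_heads = mc$n_heads,
                 d_model = mc$d_model,
                 d_ff = if (is.null(mc$d_ff)) 4L * mc$d_model else mc$d_ff,
                 mask_lambda = mc$mask_lambda,
                 mask_sparsity_lambda = mc$mask_sparsity_lambda,
                 dropout = mc$dropout, layout = mc$layout,
                 standardize = mc$standardize, seed = cfg$train$seed),
    error = function(e) cfg_error("invalid model config: ",
                                  conditionMessage(e)))
}

train_spec_from_config <- function(cfg) {
  tc <- cfg$train
  tryCatch(
    train_spec(lr = tc$lr, batch_size = tc$batch_size,
               max_epochs = tc$max_epochs, patience = tc$patience,
               split = unlist(tc$split), seed = tc$seed),
    error = function(e) cfg_error("invalid train config: ",
                                  conditionMessage(e)))
}
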