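# Single-file model checkpoint: a JSON header line (config, class labels,
# parameter shapes) followed by all parameters as raw little-endian doubles.

#' Save a model checkpoint
#'
#' @param model an `eeg_transformer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "eeg_transformer"))
  theta <- flatten_params(model$params)
  header <- jsonlite::toJSON(
    list(format = "eegadapt-checkpoint", version = 1L,
         config = unclass(model$config), classes = model$classes,
         n_params = length(theta)),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, "\n"), con, eos = NULL)
  writeBin(theta, con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_model()].
#' @return An `eeg_transformer` with the stored weights and class labels.
#' @export
load_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  hd <- jsonlite::fromJSON(header)
  if (!identical(hd$format, "eegadapt-checkpoint"))
    stop("not an eegadapt checkpoint: ", path, call. = FALSE)
  cfg <- hd$config
  config <- model_config(
    n_classes = cfg$n_classes, n_channels = cfg$n_channels,
    seq_len = cfg$seq_len, frame_dim = cfg$frame_dim,
    n_layers = cfg$n_layers, n_heads = cfg$n_heads, d_model = cfg$d_model,
    d_ff = cfg$d_ff, mask_lambda = cfg$mask_lambda,
    mask_sparsity_lambda = cfg$mask_sparsity_lambda, dropout = cfg$dropout,
    layout = cfg$layout, standardize = cfg$standardize, seed = cfg$seed)
  model <- init_model(config)
  theta <- readBin(con, "double", n = hd$n_params, size = 8L,
                   endian = "little")
  if (length(theta) != hd$n_params)
    stop("truncated checkpoint: ", path, call. = FALSE)
  model$params <- unflatten_params(model$params, theta)$value
  model$classes <- hd$classes
  model
}
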